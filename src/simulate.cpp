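#include <Rcpp.h>
using namespace Rcpp;

// Compiled session simulator. Consumes R's RNG stream with exactly the same
// draw order as the pure-R reference loop in simulate_session(engine = "r"),
// so the two paths produce bitwise-identical sessions from the same seed
// (asserted in the test suite).
//
// slot: 1 standard, 2 uncertainty, 3 follow-up (offer resolved at run time).
// std1/std2: pre-ordered (left, right) offer objects for slot-1 trials.
// ul1/ul2/ur1/ur2: (top, bottom) objects of the left and right displayed
//   pairs for slot-2 trials.
// flabel: 1 repeat, 2 switch, 3 clash for slot-3 trials.
// comm/uniq: 4x4 room-lookup tables (shared room; room of the row object not
//   shared with the column object).

// [[Rcpp::export]]
List sim_session_cpp(NumericVector par, int family, int persev_either,
                     IntegerVector slot, IntegerVector std1, IntegerVector std2,
                     IntegerVector ul1, IntegerVector ul2,
                     IntegerVector ur1, IntegerVector ur2,
                     IntegerVector flabel, NumericMatrix probs,
                     IntegerMatrix opens, IntegerMatrix comm,
                     IntegerMatrix uniq) {
  const double wmb = par[0], beta = par[1], persev = par[2], lr_mb = par[3],
               lr_std = par[4], lr_gn = par[5], lr_gr = par[6], lam = par[7],
               lr_mf = par[8];
  const bool elig = family >= 2;
  const bool pe = persev_either != 0;
  double qmf[5], qr[5], qo[5], e[5];
  for (int i = 1; i <= 4; ++i) { qmf[i] = 1.0; qr[i] = 0.5; qo[i] = 1.0; e[i] = 0.0; }
  int last1 = 0, last2 = 0;

  int openers[5][2];                    // the two objects opening each room
  for (int r = 1; r <= 4; ++r) {
    int k = 0;
    for (int o = 1; o <= 4; ++o) {
      if (opens(o - 1, 0) == r || opens(o - 1, 1) == r) openers[r][k++] = o;
    }
  }

  const int n = slot.size();
  IntegerVector o1(n, NA_INTEGER), o2(n, NA_INTEGER), o3(n, NA_INTEGER),
      o4(n, NA_INTEGER), choice(n, NA_INTEGER), chosen(n, NA_INTEGER),
      nominated(n, NA_INTEGER), room1(n, NA_INTEGER), room2(n, NA_INTEGER),
      rew1(n, NA_INTEGER), rew2(n, NA_INTEGER);
  NumericVector choice_p(n, NA_REAL);

  #define OBJ_MB(o) (family == 0 ? qr[opens((o) - 1, 0)] + qr[opens((o) - 1, 1)] \
                     : (family == 1 ? qo[(o)] : 0.0))

  for (int t = 0; t < n; ++t) {
    if (elig) for (int i = 1; i <= 4; ++i) e[i] *= lam;
    int fr, sr, r1t, r2t;
    if (slot[t] == 2) {                 // uncertainty trial
      const int l1 = ul1[t], l2 = ul2[t], rg1 = ur1[t], rg2 = ur2[t];
      o1[t] = l1; o2[t] = l2; o3[t] = rg1; o4[t] = rg2;
      const bool in1 = (l1 == last1 || l2 == last1 ||
                        (pe && (l1 == last2 || l2 == last2)));
      const bool in2 = (rg1 == last1 || rg2 == last1 ||
                        (pe && (rg1 == last2 || rg2 == last2)));
      const double v1 = wmb * 0.5 * (OBJ_MB(l1) + OBJ_MB(l2)) +
        (1.0 - wmb) * 0.5 * (qmf[l1] + qmf[l2]) + persev * (in1 ? 1.0 : 0.0);
      const double v2 = wmb * 0.5 * (OBJ_MB(rg1) + OBJ_MB(rg2)) +
        (1.0 - wmb) * 0.5 * (qmf[rg1] + qmf[rg2]) + persev * (in2 ? 1.0 : 0.0);
      const double d = beta * (v1 - v2);
      const double p1 = (d >= 0) ? 1.0 / (1.0 + std::exp(-d))
                                 : std::exp(d) / (1.0 + std::exp(d));
      choice_p[t] = p1;
      choice[t] = (unif_rand() < p1) ? 1 : 2;
      const int c1 = (choice[t] == 1) ? l1 : rg1;
      const int c2 = (choice[t] == 1) ? l2 : rg2;
      const int nom = (unif_rand() < 0.5) ? c1 : c2;   // fair ghost coin
      const int rej = c1 + c2 - nom;
      fr = comm(nom - 1, rej - 1); sr = uniq(nom - 1, rej - 1);
      r1t = (unif_rand() < probs(t, fr - 1)) ? 1 : 0;
      r2t = (unif_rand() < probs(t, sr - 1)) ? 1 : 0;
      nominated[t] = nom;
      const double tot = r1t + r2t;
      if (elig) {
        if (family == 2) { e[c1] += 1.0; e[c2] += 1.0; }
        else { e[c1] = 1.0; e[c2] = 1.0; }
        const double f = (family == 2) ? (1.0 - lam) * lr_mf : lr_mf;
        for (int i = 1; i <= 4; ++i) qmf[i] += f * e[i] * (tot - qmf[i]);
      } else {
        qmf[nom] += lr_gn * (tot - qmf[nom]);
        qmf[rej] += lr_gr * (tot - qmf[rej]);
        if (family == 0) {
          qr[fr] += lr_mb * (r1t - qr[fr]);
          qr[sr] += lr_mb * (r2t - qr[sr]);
        } else {
          qo[nom] += lr_mb * (tot - qo[nom]);
          for (int j = 1; j <= 4; ++j) {
            if (j == nom) continue;
            const bool s1 = (opens(j - 1, 0) == fr || opens(j - 1, 1) == fr);
            const bool s2 = (opens(j - 1, 0) == sr || opens(j - 1, 1) == sr);
            if (s1 != s2) qo[j] += lr_mb * ((s1 ? r1t : r2t) - 0.5 * qo[j]);
          }
        }
      }
      last1 = nom; last2 = pe ? rej : 0;
    } else {                            // standard or follow-up trial
      int A, B;
      if (slot[t] == 1) {
        A = std1[t]; B = std2[t];
      } else {
        const int pc1 = (choice[t - 1] == 1) ? o1[t - 1] : o3[t - 1];
        const int pc2 = (choice[t - 1] == 1) ? o2[t - 1] : o4[t - 1];
        const int nom = nominated[t - 1];
        const int rej = pc1 + pc2 - nom;
        if (flabel[t] == 1) {           // repeat: nominee + informative-room sharer
          const int inf_room = uniq(nom - 1, rej - 1);
          A = nom;
          B = (openers[inf_room][0] == nom) ? openers[inf_room][1]
                                            : openers[inf_room][0];
        } else if (flabel[t] == 2) {    // switch: rejected + its room sharer
          const int rej_room = uniq(rej - 1, nom - 1);
          A = rej;
          B = (openers[rej_room][0] == rej) ? openers[rej_room][1]
                                            : openers[rej_room][0];
        } else {                        // clash: the previously chosen pair
          A = pc1; B = pc2;
        }
        if (unif_rand() < 0.5) { const int tmp = A; A = B; B = tmp; }
      }
      o1[t] = A; o2[t] = B;
      const double v1 = wmb * OBJ_MB(A) + (1.0 - wmb) * qmf[A] +
        persev * ((A == last1 || (pe && A == last2)) ? 1.0 : 0.0);
      const double v2 = wmb * OBJ_MB(B) + (1.0 - wmb) * qmf[B] +
        persev * ((B == last1 || (pe && B == last2)) ? 1.0 : 0.0);
      const double d = beta * (v1 - v2);
      const double p1 = (d >= 0) ? 1.0 / (1.0 + std::exp(-d))
                                 : std::exp(d) / (1.0 + std::exp(d));
      choice_p[t] = p1;
      choice[t] = (unif_rand() < p1) ? 1 : 2;
      const int ch = (choice[t] == 1) ? A : B;
      const int other = A + B - ch;
      fr = uniq(ch - 1, other - 1); sr = comm(ch - 1, other - 1);
      r1t = (unif_rand() < probs(t, fr - 1)) ? 1 : 0;
      r2t = (unif_rand() < probs(t, sr - 1)) ? 1 : 0;
      chosen[t] = ch;
      const double tot = r1t + r2t;
      if (elig) {
        if (family == 2) e[ch] += 1.0; else e[ch] = 1.0;
        const double f = (family == 2) ? (1.0 - lam) * lr_mf : lr_mf;
        for (int i = 1; i <= 4; ++i) qmf[i] += f * e[i] * (tot - qmf[i]);
      } else {
        qmf[ch] += lr_std * (tot - qmf[ch]);
        if (family == 0) {
          qr[fr] += lr_mb * (r1t - qr[fr]);
          qr[sr] += lr_mb * (r2t - qr[sr]);
        } else {
          qo[ch] += lr_mb * (tot - qo[ch]);
          for (int j = 1; j <= 4; ++j) {
            if (j == ch) continue;
            const bool s1 = (opens(j - 1, 0) == fr || opens(j - 1, 1) == fr);
            const bool s2 = (opens(j - 1, 0) == sr || opens(j - 1, 1) == sr);
            if (s1 != s2) qo[j] += lr_mb * ((s1 ? r1t : r2t) - 0.5 * qo[j]);
          }
        }
      }
      last1 = ch; last2 = 0;
    }
    room1[t] = fr; room2[t] = sr; rew1[t] = r1t; rew2[t] = r2t;
  }
  #undef OBJ_MB

  return List::create(_["o1"] = o1, _["o2"] = o2, _["o3"] = o3, _["o4"] = o4,
                      _["choice"] = choice, _["chosen_object"] = chosen,
                      _["ghost_nominated"] = nominated,
                      _["room_1"] = room1, _["reward_1"] = rew1,
                      _["room_2"] = room2, _["reward_2"] = rew2,
                      _["choice_p"] = choice_p);
}
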