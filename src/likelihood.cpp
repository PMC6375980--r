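#include <Rcpp.h>
using namespace Rcpp;

// Compiled replay of a session's choice likelihood. Mirrors the R reference
// path (net_values / choice_prob / update operators) trial by trial; the two
// implementations are cross-checked in the test suite.
//
// par: w_mb, beta, persev, lr_mb, lr_standard, lr_ghost_nom, lr_ghost_rej,
//      lam, lr_mf (already projected onto the constraint surface).
// family: 0 mb_room, 1 mb_object, 2 elig_accumulating, 3 elig_replacing.
// persev_either: 1 if both chosen-pair members count as "last chosen" after
//      an uncertainty trial, 0 if only the nominee does.
// opens: 4 x 2 matrix of the two rooms (1-based) opened by each object.

static inline double obj_mb(int o, int family, const double *qr,
                            const double *qo, const IntegerMatrix &opens) {
  if (family == 0) return qr[opens(o - 1, 0)] + qr[opens(o - 1, 1)];
  if (family == 1) return qo[o];
  return 0.0;
}

// trials: n x 12 integer matrix with columns type, a1, a2, b1, b2, choice,
// nominee, room1, room2, r1, r2, missing (see session_arrays() in R).
// [[Rcpp::export]]
double nll_session_cpp(NumericVector par, int family, int persev_either,
                       IntegerMatrix trials, IntegerMatrix opens) {
  const double wmb = par[0], beta = par[1], persev = par[2], lr_mb = par[3],
               lr_std = par[4], lr_gn = par[5], lr_gr = par[6], lam = par[7],
               lr_mf = par[8];
  double qmf[5], qr[5], qo[5], e[5];
  for (int i = 1; i <= 4; ++i) { qmf[i] = 1.0; qr[i] = 0.5; qo[i] = 1.0; e[i] = 0.0; }
  int last1 = 0, last2 = 0;
  const bool elig = family >= 2;
  const int n = trials.nrow();
  const int *type = &trials(0, 0), *a1 = &trials(0, 1), *a2 = &trials(0, 2),
            *b1 = &trials(0, 3), *b2 = &trials(0, 4), *choice = &trials(0, 5),
            *nominee = &trials(0, 6), *room1 = &trials(0, 7),
            *room2 = &trials(0, 8), *r1 = &trials(0, 9), *r2 = &trials(0, 10),
            *missing = &trials(0, 11);
  double nll = 0.0;

  for (int t = 0; t < n; ++t) {
    if (missing[t]) continue;
    if (elig) for (int i = 1; i <= 4; ++i) e[i] *= lam;

    double v1, v2;
    if (type[t] == 0) {               // standard trial: offers in (a1, a2)
      const int A = a1[t], B = a2[t];
      v1 = wmb * obj_mb(A, family, qr, qo, opens) + (1.0 - wmb) * qmf[A] +
           persev * ((A == last1 || (persev_either && A == last2)) ? 1.0 : 0.0);
      v2 = wmb * obj_mb(B, family, qr, qo, opens) + (1.0 - wmb) * qmf[B] +
           persev * ((B == last1 || (persev_either && B == last2)) ? 1.0 : 0.0);
    } else {                           // uncertainty trial: two pairs
      const int p1a = a1[t], p1b = a2[t], p2a = b1[t], p2b = b2[t];
      const bool in1 = (p1a == last1 || p1b == last1 ||
                        (persev_either && (p1a == last2 || p1b == last2)));
      const bool in2 = (p2a == last1 || p2b == last1 ||
                        (persev_either && (p2a == last2 || p2b == last2)));
      v1 = wmb * 0.5 * (obj_mb(p1a, family, qr, qo, opens) +
                        obj_mb(p1b, family, qr, qo, opens)) +
           (1.0 - wmb) * 0.5 * (qmf[p1a] + qmf[p1b]) + persev * (in1 ? 1.0 : 0.0);
      v2 = wmb * 0.5 * (obj_mb(p2a, family, qr, qo, opens) +
                        obj_mb(p2b, family, qr, qo, opens)) +
           (1.0 - wmb) * 0.5 * (qmf[p2a] + qmf[p2b]) + persev * (in2 ? 1.0 : 0.0);
    }
    const double d = beta * ((choice[t] == 1) ? (v1 - v2) : (v2 - v1));
    nll += (d >= 0) ? log1p(std::exp(-d)) : (-d + log1p(std::exp(d)));

    const double tot = r1[t] + r2[t];
    if (type[t] == 0) {
      const int ch = (choice[t] == 1) ? a1[t] : a2[t];
      if (elig) {
        e[ch] = (family == 2) ? 1.0 + e[ch] : 1.0;
        const double f = (family == 2) ? (1.0 - lam) * lr_mf : lr_mf;
        for (int i = 1; i <= 4; ++i) qmf[i] += f * e[i] * (tot - qmf[i]);
      } else {
        qmf[ch] += lr_std * (tot - qmf[ch]);
        if (family == 0) {
          qr[room1[t]] += lr_mb * (r1[t] - qr[room1[t]]);
          qr[room2[t]] += lr_mb * (r2[t] - qr[room2[t]]);
        } else {
          qo[ch] += lr_mb * (tot - qo[ch]);
          for (int j = 1; j <= 4; ++j) {
            if (j == ch) continue;
            const int ja = opens(j - 1, 0), jb = opens(j - 1, 1);
            const bool s1 = (ja == room1[t] || jb == room1[t]);
            const bool s2 = (ja == room2[t] || jb == room2[t]);
            if (s1 != s2) {           // shares exactly one observed room
              const double rr = s1 ? r1[t] : r2[t];
              qo[j] += lr_mb * (rr - 0.5 * qo[j]);
            }
          }
        }
      }
      last1 = ch; last2 = 0;
    } else {
      const int c1 = (choice[t] == 1) ? a1[t] : b1[t];
      const int c2 = (choice[t] == 1) ? a2[t] : b2[t];
      const int nom = nominee[t];
      const int rej = (nom == c1) ? c2 : c1;
      if (elig) {                      // both chosen-pair traces updated
        if (family == 2) { e[c1] = 1.0 + e[c1]; e[c2] = 1.0 + e[c2]; }
        else { e[c1] = 1.0; e[c2] = 1.0; }
        const double f = (family == 2) ? (1.0 - lam) * lr_mf : lr_mf;
        for (int i = 1; i <= 4; ++i) qmf[i] += f * e[i] * (tot - qmf[i]);
      } else {
        qmf[nom] += lr_gn * (tot - qmf[nom]);
        qmf[rej] += lr_gr * (tot - qmf[rej]);
        if (family == 0) {
          qr[room1[t]] += lr_mb * (r1[t] - qr[room1[t]]);
          qr[room2[t]] += lr_mb * (r2[t] - qr[room2[t]]);
        } else {
          qo[nom] += lr_mb * (tot - qo[nom]);
          for (int j = 1; j <= 4; ++j) {
            if (j == nom) continue;
            const int ja = opens(j - 1, 0), jb = opens(j - 1, 1);
            const bool s1 = (ja == room1[t] || jb == room1[t]);
            const bool s2 = (ja == room2[t] || jb == room2[t]);
            if (s1 != s2) {
              const double rr = s1 ? r1[t] : r2[t];
              qo[j] += lr_mb * (rr - 0.5 * qo[j]);
            }
          }
        }
      }
      last1 = nom; last2 = persev_either ? rej : 0;
    }
  }
  return nll;
}
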