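#include <Rcpp.h>
using namespace Rcpp;

// Term type codes shared with R/terms.R (keep in sync):
//  0 edges/sum   1 mutual      2 transitive  3 cyclical
//  4 nodematch   5 nodemix     6 sender      7 nodecov     8 absdiff
//
// Binary transitive counts ordered triples (i,j,k) with arcs i->j, j->k,
// i->k; binary cyclical counts distinct 3-cycles (ordered-triple sum / 3).
// Valued transitive/cyclical use the min-within-path, max-over-paths
// transform: sum over ordered pairs (p,q) of
//   transitive: min(y[p,q], max_m min(y[p,m], y[m,q]))
//   cyclical:   min(y[q,p], max_m min(y[p,m], y[m,q]))

static inline int imin(int a, int b) { return a < b ? a : b; }
static inline int imax(int a, int b) { return a > b ? a : b; }

struct Terms {
  std::vector<int> type;
  std::vector<NumericVector> x;
  std::vector<NumericVector> z;
  int p;
};

static Terms unpack_terms(const IntegerVector& type, const List& xs, const List& zs) {
  Terms tm;
  tm.p = type.size();
  for (int t = 0; t < tm.p; ++t) {
    tm.type.push_back(type[t]);
    tm.x.push_back(as<NumericVector>(xs[t]));
    tm.z.push_back(as<NumericVector>(zs[t]));
  }
  return tm;
}

// strongest two-path p -> m -> q under min, maximised over m
static int best_twopath(const IntegerMatrix& y, int n, int p, int q) {
  int best = 0;
  for (int m = 0; m < n; ++m) {
    if (m == p || m == q) continue;
    int s = imin(y(p, m), y(m, q));
    if (s > best) best = s;
  }
  return best;
}

static double valued_triad_contrib(const IntegerMatrix& y, int n, int p, int q,
                                   bool cyclical) {
  int base = cyclical ? y(q, p) : y(p, q);
  if (base == 0) return 0.0;
  return (double)imin(base, best_twopath(y, n, p, q));
}

static double stat_one(const IntegerMatrix& y, int n, bool directed, bool valued,
                       int type, const NumericVector& x, const NumericVector& z) {
  double s = 0.0;
  switch (type) {
  case 0: // edges / sum
    for (int i = 0; i < n; ++i)
      for (int j = (directed ? 0 : i + 1); j < n; ++j)
        if (i != j) s += y(i, j);
    return s;
  case 1: // mutual
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        s += imin(y(i, j), y(j, i));
    return s;
  case 2: // transitive
    if (!valued) {
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          if (j == i || !y(i, j)) continue;
          for (int k = 0; k < n; ++k) {
            if (k == i || k == j) continue;
            if (y(j, k) && y(i, k)) s += 1.0;
          }
        }
      return s;
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < n; ++k)
        if (k != i) s += valued_triad_contrib(y, n, i, k, false);
    return s;
  case 3: // cyclical
    if (!valued) {
      for (int i = 0; i < n; ++i)
        for (int j = 0; j < n; ++j) {
          if (j == i || !y(i, j)) continue;
          for (int k = 0; k < n; ++k) {
            if (k == i || k == j) continue;
            if (y(j, k) && y(k, i)) s += 1.0;
          }
        }
      return s / 3.0;
    }
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < n; ++k)
        if (k != i) s += valued_triad_contrib(y, n, i, k, true);
    return s;
  case 4: // nodematch
    for (int i = 0; i < n; ++i)
      for (int j = (directed ? 0 : i + 1); j < n; ++j)
        if (i != j) s += y(i, j) * x[i] * x[j];
    return s;
  case 5: // nodemix (directed)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) s += y(i, j) * x[i] * z[j];
    return s;
  case 6: // sender covariate (directed)
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j) s += y(i, j) * x[i];
    return s;
  case 7: // node covariate
    for (int i = 0; i < n; ++i)
      for (int j = (directed ? 0 : i + 1); j < n; ++j)
        if (i != j) s += y(i, j) * (x[i] + x[j]);
    return s;
  case 8: // absolute difference
    for (int i = 0; i < n; ++i)
      for (int j = (directed ? 0 : i + 1); j < n; ++j)
        if (i != j) s += y(i, j) * std::abs(x[i] - x[j]);
    return s;
  }
  stop("unknown term type");
  return 0.0;
}

static void stats_all(const IntegerMatrix& y, int n, bool directed, bool valued,
                      const Terms& tm, double* out) {
  for (int t = 0; t < tm.p; ++t)
    out[t] = stat_one(y, n, directed, valued, tm.type[t], tm.x[t], tm.z[t]);
}

// local recompute of a valued triad term over every base pair whose
// contribution can involve dyad (i,j) (or (j,i)): rows and columns i, j
static double valued_triad_local(const IntegerMatrix& y, int n, int i, int j,
                                 bool cyclical) {
  double s = 0.0;
  std::vector<char> seen((size_t)n * n, 0);
  int is[2] = { i, j };
  for (int a = 0; a < 2; ++a) {
    int u = is[a];
    for (int q = 0; q < n; ++q) {
      if (q == u) continue;
      if (!seen[(size_t)u * n + q]) {
        seen[(size_t)u * n + q] = 1;
        s += valued_triad_contrib(y, n, u, q, cyclical);
      }
      if (!seen[(size_t)q * n + u]) {
        seen[(size_t)q * n + u] = 1;
        s += valued_triad_contrib(y, n, q, u, cyclical);
      }
    }
  }
  return s;
}

// Profile of a directed valued triad statistic restricted to the base
// pairs that involve dyad (i,j), as a function of y[i,j] = v, v = 0..vmax.
// O(n^2 + n*vmax): per affected base the two-path maximum excluding the
// changing leg is computed once, after which each v costs O(1).
static void triad_profile_directed(const IntegerMatrix& y, int n, int i, int j,
                                   int vmax, bool cyclical, double* prof) {
  for (int v = 0; v <= vmax; ++v) prof[v] = 0.0;
  if (!cyclical) {
    // base (i,j): min(v, best two-path i->m->j)
    int M = best_twopath(y, n, i, j);
    for (int v = 0; v <= vmax; ++v) prof[v] += imin(v, M);
    // bases (i,q): leg i->j->q
    for (int q = 0; q < n; ++q) {
      if (q == i || q == j) continue;
      int inner = y(i, q);
      if (!inner) continue;
      int Mrest = 0;
      for (int m = 0; m < n; ++m) {
        if (m == i || m == q || m == j) continue;
        Mrest = imax(Mrest, imin(y(i, m), y(m, q)));
      }
      int leg = y(j, q);
      for (int v = 0; v <= vmax; ++v)
        prof[v] += imin(inner, imax(Mrest, imin(v, leg)));
    }
    // bases (p,j): leg p->i->j
    for (int p = 0; p < n; ++p) {
      if (p == i || p == j) continue;
      int inner = y(p, j);
      if (!inner) continue;
      int Mrest = 0;
      for (int m = 0; m < n; ++m) {
        if (m == p || m == j || m == i) continue;
        Mrest = imax(Mrest, imin(y(p, m), y(m, j)));
      }
      int leg = y(p, i);
      for (int v = 0; v <= vmax; ++v)
        prof[v] += imin(inner, imax(Mrest, imin(leg, v)));
    }
  } else {
    // base (j,i): y[i,j] is the closing arc
    int M = best_twopath(y, n, j, i);
    for (int v = 0; v <= vmax; ++v) prof[v] += imin(v, M);
    // bases (i,q): path i->j->q closed by q->i
    for (int q = 0; q < n; ++q) {
      if (q == i || q == j) continue;
      int closing = y(q, i);
      if (!closing) continue;
      int Mrest = 0;
      for (int m = 0; m < n; ++m) {
        if (m == i || m == q || m == j) continue;
        Mrest = imax(Mrest, imin(y(i, m), y(m, q)));
      }
      int leg = y(j, q);
      for (int v = 0; v <= vmax; ++v)
        prof[v] += imin(closing, imax(Mrest, imin(v, leg)));
    }
    // bases (p,j): path p->i->j closed by j->p
    for (int p = 0; p < n; ++p) {
      if (p == i || p == j) continue;
      int closing = y(j, p);
      if (!closing) continue;
      int Mrest = 0;
      for (int m = 0; m < n; ++m) {
        if (m == p || m == j || m == i) continue;
        Mrest = imax(Mrest, imin(y(p, m), y(m, j)));
      }
      int leg = y(p, i);
      for (int v = 0; v <= vmax; ++v)
        prof[v] += imin(closing, imax(Mrest, imin(leg, v)));
    }
  }
}

// change in all statistics when dyad (i,j) is set to v (both directions
// for undirected networks); y restored on exit
static void change_stats(IntegerMatrix& y, int n, bool directed, bool valued,
                         const Terms& tm, int i, int j, int v, double* delta) {
  int w = y(i, j);
  double d = (double)(v - w);
  for (int t = 0; t < tm.p; ++t) {
    int type = tm.type[t];
    const NumericVector& x = tm.x[t];
    const NumericVector& z = tm.z[t];
    switch (type) {
    case 0:
      delta[t] = d; break;
    case 1: { // mutual (binary directed)
      int o = y(j, i);
      delta[t] = (double)(imin(v, o) - imin(w, o));
      break;
    }
    case 2:
    case 3: {
      bool cyc = (type == 3);
      if (!valued) {
        if (directed) {
          double c = 0.0;
          if (!cyc) {
            for (int k = 0; k < n; ++k) {
              if (k == i || k == j) continue;
              if (y(j, k) && y(i, k)) c += 1.0; // (i,j,k)
              if (y(k, i) && y(k, j)) c += 1.0; // (k,i,j)
              if (y(i, k) && y(k, j)) c += 1.0; // (i,k,j)
            }
          } else {
            for (int k = 0; k < n; ++k) {
              if (k == i || k == j) continue;
              if (y(j, k) && y(k, i)) c += 1.0; // closes i->j->k->i
            }
          }
          delta[t] = d * c;
        } else {
          // undirected binary: triangles through the pair
          double c = 0.0;
          for (int k = 0; k < n; ++k) {
            if (k == i || k == j) continue;
            if (y(i, k) && y(j, k)) c += 1.0;
          }
          delta[t] = d * c;
        }
      } else if (directed) {
        double prof_w, prof_v;
        std::vector<double> prof(imax(v, w) + 1);
        triad_profile_directed(y, n, i, j, imax(v, w), cyc, &prof[0]);
        prof_w = prof[w]; prof_v = prof[v];
        delta[t] = prof_v - prof_w;
      } else {
        double before = valued_triad_local(y, n, i, j, cyc);
        y(i, j) = v; y(j, i) = v;
        double after = valued_triad_local(y, n, i, j, cyc);
        y(i, j) = w; y(j, i) = w;
        delta[t] = after - before;
      }
      break;
    }
    case 4:
      delta[t] = d * x[i] * x[j]; break;
    case 5:
      delta[t] = d * x[i] * z[j]; break;
    case 6:
      delta[t] = d * x[i]; break;
    case 7:
      delta[t] = d * (x[i] + x[j]); break;
    case 8:
      delta[t] = d * std::abs(x[i] - x[j]); break;
    default:
      stop("unknown term type");
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_stats(IntegerMatrix y, bool directed, bool valued,
                        IntegerVector type, List xs, List zs) {
  int n = y.nrow();
  Terms tm = unpack_terms(type, xs, zs);
  NumericVector out(tm.p);
  stats_all(y, n, directed, valued, tm, REAL(out));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_changestat(IntegerMatrix y, bool directed, bool valued,
                             IntegerVector type, List xs, List zs,
                             int i, int j, int v) {
  IntegerMatrix yc = clone(y);
  int n = yc.nrow();
  Terms tm = unpack_terms(type, xs, zs);
  NumericVector out(tm.p);
  change_stats(yc, n, directed, valued, tm, i - 1, j - 1, v, REAL(out));
  return out;
}

// Per-dyad statistic table for pseudolikelihood: for each free dyad, the
// statistic change of setting it to v = 0..vmax relative to v = 0,
// holding the rest of the network at its observed state.
// [[Rcpp::export]]
List cpp_dyad_table(IntegerMatrix y, bool directed, bool valued,
                    IntegerVector type, List xs, List zs, int vmax) {
  IntegerMatrix yc = clone(y);
  int n = yc.nrow();
  Terms tm = unpack_terms(type, xs, zs);
  int p = tm.p;
  std::vector<std::pair<int,int> > dyads;
  for (int i = 0; i < n; ++i)
    for (int j = (directed ? 0 : i + 1); j < n; ++j)
      if (i != j) dyads.push_back(std::make_pair(i, j));
  int nd = dyads.size();
  NumericVector tab(Dimension(nd, vmax + 1, p));
  IntegerVector yobs(nd);
  IntegerMatrix ij(nd, 2);
  std::vector<double> d0(p), dv(p);
  for (int d = 0; d < nd; ++d) {
    int i = dyads[d].first, j = dyads[d].second;
    yobs[d] = yc(i, j);
    ij(d, 0) = i + 1; ij(d, 1) = j + 1;
    change_stats(yc, n, directed, valued, tm, i, j, 0, &d0[0]);
    for (int v = 0; v <= vmax; ++v) {
      change_stats(yc, n, directed, valued, tm, i, j, v, &dv[0]);
      for (int t = 0; t < p; ++t)
        tab[d + nd * (v + (vmax + 1) * t)] = dv[t] - d0[t];
    }
  }
  return List::create(_["delta"] = tab, _["yobs"] = yobs, _["dyads"] = ij);
}

// statistic profile S_t(v) (up to a constant not depending on v) for one
// dyad of a count network; used by the Gibbs sampler
static void count_profiles(IntegerMatrix& y, int n, bool directed,
                           const Terms& tm, int i, int j, int vmax,
                           std::vector<double>& prof /* p x (vmax+1) */) {
  int w = y(i, j);
  for (int t = 0; t < tm.p; ++t) {
    double* pt = &prof[(size_t)t * (vmax + 1)];
    int type = tm.type[t];
    const NumericVector& x = tm.x[t];
    const NumericVector& z = tm.z[t];
    double c;
    switch (type) {
    case 0: c = 1.0; break;
    case 4: c = x[i] * x[j]; break;
    case 5: c = x[i] * z[j]; break;
    case 6: c = x[i]; break;
    case 7: c = x[i] + x[j]; break;
    case 8: c = std::abs(x[i] - x[j]); break;
    case 2:
    case 3: {
      bool cyc = (type == 3);
      if (directed) {
        triad_profile_directed(y, n, i, j, vmax, cyc, pt);
      } else {
        for (int v = 0; v <= vmax; ++v) {
          y(i, j) = v; y(j, i) = v;
          pt[v] = valued_triad_local(y, n, i, j, cyc);
        }
        y(i, j) = w; y(j, i) = w;
      }
      continue;
    }
    default:
      stop("term not supported in count models");
    }
    for (int v = 0; v <= vmax; ++v) pt[v] = c * v;
  }
}

// Sampler. Binary: Metropolis-Hastings single-dyad toggles with
// acceptance exp(theta . delta). Count: random-scan Gibbs, resampling a
// uniformly chosen dyad from its full conditional under the Poisson
// reference, evaluated on support 0..vmax. One retained draw every
// `interval` updates after `burnin`. Uses R's RNG (seed from R).
// [[Rcpp::export]]
List cpp_ergm_sample(IntegerMatrix y0, bool directed, bool valued,
                     IntegerVector type, List xs, List zs,
                     NumericVector theta, int burnin, int interval,
                     int nsamp, bool collect_nets, int vmax) {
  IntegerMatrix y = clone(y0);
  int n = y.nrow();
  Terms tm = unpack_terms(type, xs, zs);
  int p = tm.p;
  std::vector<double> g(p), delta(p);
  stats_all(y, n, directed, valued, tm, &g[0]);

  std::vector<std::pair<int,int> > dyads;
  for (int i = 0; i < n; ++i)
    for (int j = (directed ? 0 : i + 1); j < n; ++j)
      if (i != j) dyads.push_back(std::make_pair(i, j));
  int nd = dyads.size();
  if (nd == 0) stop("network has no free dyads");
  if (valued) {
    int ymax = 0;
    for (int d = 0; d < nd; ++d)
      ymax = imax(ymax, y(dyads[d].first, dyads[d].second));
    if (vmax < ymax) stop("vmax below an observed count");
  }

  std::vector<double> lfact(vmax + 1), lmass(vmax + 1),
    prof((size_t)p * (vmax + 1));
  lfact[0] = 0.0;
  for (int v = 1; v <= vmax; ++v) lfact[v] = lfact[v - 1] + std::log((double)v);

  NumericMatrix stats(nsamp, p);
  List nets(collect_nets ? nsamp : 0);
  long total = (long)burnin + (long)interval * nsamp;
  int taken = 0;
  long next_keep = burnin + interval;

  for (long it = 1; it <= total; ++it) {
    int d = (int)(R::unif_rand() * nd);
    if (d == nd) d = nd - 1;
    int i = dyads[d].first, j = dyads[d].second;
    int w = y(i, j);
    if (!valued) {
      int v = 1 - w;
      change_stats(y, n, directed, valued, tm, i, j, v, &delta[0]);
      double logacc = 0.0;
      for (int t = 0; t < p; ++t) logacc += theta[t] * delta[t];
      if (logacc >= 0.0 || R::unif_rand() < std::exp(logacc)) {
        y(i, j) = v;
        if (!directed) y(j, i) = v;
        for (int t = 0; t < p; ++t) g[t] += delta[t];
      }
    } else {
      count_profiles(y, n, directed, tm, i, j, vmax, prof);
      double mx = -1e300;
      for (int v = 0; v <= vmax; ++v) {
        double lm = -lfact[v];
        for (int t = 0; t < p; ++t) lm += theta[t] * prof[(size_t)t * (vmax + 1) + v];
        lmass[v] = lm;
        if (lm > mx) mx = lm;
      }
      double tot = 0.0;
      for (int v = 0; v <= vmax; ++v) { lmass[v] = std::exp(lmass[v] - mx); tot += lmass[v]; }
      double u = R::unif_rand() * tot, acc = 0.0;
      int v = vmax;
      for (int k = 0; k <= vmax; ++k) { acc += lmass[k]; if (u <= acc) { v = k; break; } }
      if (v != w) {
        for (int t = 0; t < p; ++t)
          g[t] += prof[(size_t)t * (vmax + 1) + v] - prof[(size_t)t * (vmax + 1) + w];
        y(i, j) = v;
        if (!directed) y(j, i) = v;
      }
    }
    if (it == next_keep) {
      for (int t = 0; t < p; ++t) stats(taken, t) = g[t];
      if (collect_nets) nets[taken] = clone(y);
      ++taken; next_keep += interval;
    }
  }
  return List::create(_["stats"] = stats, _["nets"] = nets,
                      _["final"] = y);
}

// (I, SI) of an ordering: inconsistent dyads and their summed rank
// differences; hot path of the I&SI hill climb
// [[Rcpp::export]]
IntegerVector cpp_inconsistencies(IntegerMatrix wins, IntegerVector ord) {
  int n = ord.size();
  int I = 0, SI = 0;
  for (int p = 0; p < n; ++p) {
    int hi = ord[p] - 1;
    for (int q = p + 1; q < n; ++q) {
      int lo = ord[q] - 1;
      if (wins(lo, hi) > wins(hi, lo)) { ++I; SI += q - p; }
    }
  }
  return IntegerVector::create(I, SI);
}
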