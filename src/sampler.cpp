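// MCMC core for sampling the augmented state (tree topology + node times,
// internal-node haplotypes, theta, rho) at a genomic focal point.
//
// Representation (0-based): tips 0..n-1 at time 0, internal nodes n..m-1
// (m = 2n-1), parent[root] = -1, children c1/c2 = -1 for tips.
//
// Emission model: marker j at bp distance d_j from the focal point is linked
// to the focal genealogy with probability w_j = exp(-(rho/2) d_j T), where T
// is the tree's total branch length (the product over branches of the
// per-branch linkage probabilities exp(-(rho/2) d t_b)). A linked marker's
// allele column follows a symmetric two-state mutation chain along the tree
// (flip probability (1 - exp(-theta t))/2 per branch of duration t; root
// allele from the marker's sample frequency). An unlinked marker's column is
// iid from the sample frequency at every node. Recombination breakpoints are
// integrated out by this mixture.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct Chain {
  int n, m, L;
  std::vector<int> parent, c1, c2;
  std::vector<double> time;
  std::vector<int> hap;  // hap[v + m*j]
  double theta, rho;
  int root;

  // data + priors
  std::vector<double> freq, dist;
  double th_lo, th_hi, r_shape, r_scale;

  // cached pieces of the log target
  std::vector<double> chain_bm;   // per (branch child v, marker j): mutation
                                  // chain term; root row fixed at 0
  std::vector<double> chainS;     // per marker: sum of chain_bm over branches
  std::vector<double> rootchain;  // per marker: log freq term of root allele
  std::vector<double> freqS;      // per marker: sum over ALL nodes of log
                                  // freq terms (unlinked explanation)
  double ttot, coal, ratepr, total;
};

double chain_term(const Chain& ch, int v, int j, double theta) {
  int p = ch.parent[v];
  double t = ch.time[p] - ch.time[v];
  double emt = std::exp(-theta * t);
  bool same = ch.hap[v + ch.m * j] == ch.hap[p + ch.m * j];
  return std::log(0.5 * (same ? (1.0 + emt) : (1.0 - emt)));
}

double freq_term(const Chain& ch, int v, int j) {
  return std::log(ch.hap[v + ch.m * j] ? ch.freq[j] : 1.0 - ch.freq[j]);
}

double total_branch_length(const Chain& ch) {
  double s = 0.0;
  for (int v = 0; v < ch.m; v++)
    if (v != ch.root) s += ch.time[ch.parent[v]] - ch.time[v];
  return s;
}

double coal_lp_of(const Chain& ch) {
  std::vector<double> tm(ch.time.begin() + ch.n, ch.time.end());
  std::sort(tm.begin(), tm.end());
  double lp = 0.0, prev = 0.0;
  int k = ch.n;
  for (size_t i = 0; i < tm.size(); i++) {
    lp -= 0.5 * k * (k - 1) * (tm[i] - prev);
    prev = tm[i];
    k--;
  }
  return lp;
}

double rate_lp_of(const Chain& ch) {
  if (ch.theta < ch.th_lo || ch.theta > ch.th_hi || ch.rho <= 0)
    return R_NegInf;
  double lp = -std::log(ch.th_hi - ch.th_lo);
  lp += R::dgamma(ch.rho, ch.r_shape, ch.r_scale, 1);
  return lp;
}

// log( w * exp(lchain) + (1-w) * exp(lfreq) ) with log(w) = lw <= 0
double column_ll(double lw, double lchain, double lfreq) {
  if (lw >= 0) return lchain;  // d = 0: fully linked
  double one_m = -std::expm1(lw);  // 1 - w, accurate near w = 1
  double a = lw + lchain;
  double b = std::log(one_m) + lfreq;
  double hi = std::max(a, b);
  if (!R_finite(hi)) return hi;
  return hi + std::log1p(std::exp(std::min(a, b) - hi));
}

double data_ll_of(const Chain& ch, double rho, const std::vector<double>& chainS,
                  const std::vector<double>& rootchain,
                  const std::vector<double>& freqS, double ttot) {
  double s = 0.0;
  for (int j = 0; j < ch.L; j++) {
    double lw = -0.5 * rho * ch.dist[j] * ttot;
    s += column_ll(lw, chainS[j] + rootchain[j], freqS[j]);
  }
  return s;
}

void recompute_all(Chain& ch) {
  ch.chain_bm.assign((size_t)ch.m * std::max(ch.L, 1), 0.0);
  ch.chainS.assign(ch.L, 0.0);
  ch.rootchain.assign(ch.L, 0.0);
  ch.freqS.assign(ch.L, 0.0);
  for (int j = 0; j < ch.L; j++) {
    for (int v = 0; v < ch.m; v++) {
      if (v != ch.root) {
        double ct = chain_term(ch, v, j, ch.theta);
        ch.chain_bm[v + ch.m * j] = ct;
        ch.chainS[j] += ct;
      }
      ch.freqS[j] += freq_term(ch, v, j);
    }
    ch.rootchain[j] = freq_term(ch, ch.root, j);
  }
  ch.ttot = total_branch_length(ch);
  ch.coal = coal_lp_of(ch);
  ch.ratepr = rate_lp_of(ch);
  ch.total = ch.coal + ch.ratepr +
             data_ll_of(ch, ch.rho, ch.chainS, ch.rootchain, ch.freqS, ch.ttot);
}

int find_root(const std::vector<int>& parent) {
  for (size_t v = 0; v < parent.size(); v++)
    if (parent[v] < 0) return (int)v;
  return -1;
}

// ---- proposal kernels -----------------------------------------------------
// Each mutates the chain state (not the caches) and reports forward/reverse
// log proposal densities plus the set of nodes whose branch term changed.

struct Prop {
  double lqf = 0.0, lqr = 0.0;
  std::vector<int> dirty;   // children whose chain term must be recomputed
  bool all_dirty = false;   // theta moves touch every chain term
  bool topo = false;        // node times changed
  int flip_u = -1, flip_j = -1;  // haplotype flip location
};

void propose_theta(Chain& ch, double delta, Prop& pr) {
  double u = R::runif(-delta, delta);
  double tn = ch.theta * std::exp(u);
  pr.lqf = -std::log(2.0 * delta) - std::log(tn);
  pr.lqr = -std::log(2.0 * delta) - std::log(ch.theta);
  ch.theta = tn;
  pr.all_dirty = true;
}

void propose_rho(Chain& ch, double delta, Prop& pr) {
  double u = R::runif(-delta, delta);
  double rn = ch.rho * std::exp(u);
  pr.lqf = -std::log(2.0 * delta) - std::log(rn);
  pr.lqr = -std::log(2.0 * delta) - std::log(ch.rho);
  ch.rho = rn;
  // only the mixture weights change; handled at evaluation time
}

void propose_flip(Chain& ch, Prop& pr) {
  int nint = ch.n - 1;
  int fu = ch.n + (int)std::floor(unif_rand() * nint);
  if (fu >= ch.m) fu = ch.m - 1;
  int fj = (int)std::floor(unif_rand() * ch.L);
  if (fj >= ch.L) fj = ch.L - 1;
  ch.hap[fu + ch.m * fj] = 1 - ch.hap[fu + ch.m * fj];
  double lq = -std::log((double)nint * ch.L);
  pr.lqf = lq;
  pr.lqr = lq;
  pr.flip_u = fu;
  pr.flip_j = fj;
  if (fu != ch.root) pr.dirty.push_back(fu);
  pr.dirty.push_back(ch.c1[fu]);
  pr.dirty.push_back(ch.c2[fu]);
}

void resample_root_time(Chain& ch, Prop& pr) {
  // degenerate topology move for n = 2: redraw the single coalescence time
  double told = ch.time[ch.root];
  double tn = R::exp_rand();
  pr.lqf = -tn;
  pr.lqr = -told;
  ch.time[ch.root] = tn;
  pr.dirty.push_back(ch.c1[ch.root]);
  pr.dirty.push_back(ch.c2[ch.root]);
  pr.topo = true;
}

// nearest-neighbour style move: swap one child of an internal non-root node
// with the node's sibling, then redraw the node's time in its valid interval
void propose_local(Chain& ch, Prop& pr) {
  if (ch.n == 2) {
    resample_root_time(ch, pr);
    return;
  }
  int nelig = ch.n - 2;
  int idx = (int)std::floor(unif_rand() * nelig);
  if (idx >= nelig) idx = nelig - 1;
  int v = -1;
  for (int w = ch.n; w < ch.m; w++) {
    if (w == ch.root) continue;
    if (idx-- == 0) { v = w; break; }
  }
  int p = ch.parent[v];
  int s = (ch.c1[p] == v) ? ch.c2[p] : ch.c1[p];
  bool first = unif_rand() < 0.5;
  int c = first ? ch.c1[v] : ch.c2[v];
  int k = first ? ch.c2[v] : ch.c1[v];
  // swap c and s
  if (first) ch.c1[v] = s; else ch.c2[v] = s;
  if (ch.c1[p] == s) ch.c1[p] = c; else ch.c2[p] = c;
  ch.parent[s] = v;
  ch.parent[c] = p;
  double hi = ch.time[p];
  double lo = std::max(ch.time[k], ch.time[s]);
  double lo_r = std::max(ch.time[k], ch.time[c]);
  double tn = R::runif(lo, hi);
  pr.lqf = -std::log(hi - lo);
  pr.lqr = -std::log(hi - lo_r);
  ch.time[v] = tn;
  pr.dirty.push_back(v);
  pr.dirty.push_back(s);
  pr.dirty.push_back(c);
  pr.dirty.push_back(k);
  pr.topo = true;
}

// subtree-prune-regraft: detach a uniformly chosen non-root subtree, reattach
// on a uniformly chosen compatible branch (or above the root), with the new
// attachment time uniform in the branch's valid interval (exponential above
// the root)
void propose_spr(Chain& ch, Prop& pr) {
  if (ch.n == 2) {
    resample_root_time(ch, pr);
    return;
  }
  int idx = (int)std::floor(unif_rand() * (ch.m - 1));
  if (idx >= ch.m - 1) idx = ch.m - 2;
  int v = (idx < ch.root) ? idx : idx + 1;
  int p = ch.parent[v];
  int s = (ch.c1[p] == v) ? ch.c2[p] : ch.c1[p];
  int g = ch.parent[p];
  double tp_old = ch.time[p];

  // detach: remove p, promoting s
  if (g >= 0) {
    if (ch.c1[g] == p) ch.c1[g] = s; else ch.c2[g] = s;
    ch.parent[s] = g;
  } else {
    ch.parent[s] = -1;
  }
  int pruned_root = (g >= 0) ? ch.root : s;

  // mark the detached subtree
  std::vector<char> inV(ch.m, 0);
  std::vector<int> stack{v};
  while (!stack.empty()) {
    int w = stack.back();
    stack.pop_back();
    inV[w] = 1;
    if (ch.c1[w] >= 0) { stack.push_back(ch.c1[w]); stack.push_back(ch.c2[w]); }
  }

  // compatible target edges in the pruned tree (identified by their child)
  std::vector<int> cand;
  for (int c = 0; c < ch.m; c++) {
    if (c == p || c == pruned_root || inV[c]) continue;
    int pc = ch.parent[c];
    if (pc < 0 || pc == p) continue;
    if (ch.time[pc] > std::max(ch.time[v], ch.time[c])) cand.push_back(c);
  }
  // K is identical for the forward and reverse move: detaching v from the
  // proposed state yields the same pruned tree and the same time[v]
  int K = (int)cand.size() + 1;
  int pick = (int)std::floor(unif_rand() * K);
  if (pick >= K) pick = K - 1;

  double lqf_t, u;
  int attached_child;
  if (pick < (int)cand.size()) {
    int c = cand[pick];
    int pc = ch.parent[c];
    double lo = std::max(ch.time[v], ch.time[c]);
    u = R::runif(lo, ch.time[pc]);
    lqf_t = -std::log(ch.time[pc] - lo);
    if (ch.c1[pc] == c) ch.c1[pc] = p; else ch.c2[pc] = p;
    ch.parent[p] = pc;
    ch.c1[p] = c;
    ch.c2[p] = v;
    ch.parent[c] = p;
    ch.parent[v] = p;
    attached_child = c;
  } else {
    int r = pruned_root;
    double base = std::max(ch.time[v], ch.time[r]);
    u = base + R::exp_rand();
    lqf_t = -(u - base);
    ch.parent[p] = -1;
    ch.c1[p] = r;
    ch.c2[p] = v;
    ch.parent[r] = p;
    ch.parent[v] = p;
    attached_child = r;
  }
  ch.time[p] = u;
  ch.root = find_root(ch.parent);

  double lqr_t;
  if (g >= 0) {
    double lo_r = std::max(ch.time[v], ch.time[s]);
    lqr_t = -std::log(ch.time[g] - lo_r);
  } else {
    double base_r = std::max(ch.time[v], ch.time[s]);
    lqr_t = -(tp_old - base_r);
  }
  double lchoice = -std::log((double)(ch.m - 1)) - std::log((double)K);
  pr.lqf = lchoice + lqf_t;
  pr.lqr = lchoice + lqr_t;
  pr.dirty.push_back(v);
  pr.dirty.push_back(s);
  pr.dirty.push_back(p);
  pr.dirty.push_back(attached_child);
  pr.topo = true;
}

Chain make_chain(IntegerVector parent, IntegerVector child1,
                 IntegerVector child2, NumericVector time, IntegerMatrix hap,
                 NumericVector freq, NumericVector dist, double theta,
                 double rho, NumericVector theta_prior,
                 NumericVector rho_prior) {
  Chain ch;
  ch.m = parent.size();
  ch.n = (ch.m + 1) / 2;
  ch.L = freq.size();
  ch.parent.assign(parent.begin(), parent.end());
  ch.c1.assign(child1.begin(), child1.end());
  ch.c2.assign(child2.begin(), child2.end());
  ch.time.assign(time.begin(), time.end());
  ch.hap.assign(hap.begin(), hap.end());
  ch.freq.assign(freq.begin(), freq.end());
  ch.dist.assign(dist.begin(), dist.end());
  ch.theta = theta;
  ch.rho = rho;
  ch.th_lo = theta_prior[0];
  ch.th_hi = theta_prior[1];
  ch.r_shape = rho_prior[0];
  ch.r_scale = rho_prior[1];
  ch.root = find_root(ch.parent);
  return ch;
}

List state_of(const Chain& ch, int L) {
  return List::create(
      _["parent"] = IntegerVector(ch.parent.begin(), ch.parent.end()),
      _["child1"] = IntegerVector(ch.c1.begin(), ch.c1.end()),
      _["child2"] = IntegerVector(ch.c2.begin(), ch.c2.end()),
      _["time"] = NumericVector(ch.time.begin(), ch.time.end()),
      _["hap"] = IntegerMatrix(ch.m, L, ch.hap.begin()),
      _["theta"] = ch.theta, _["rho"] = ch.rho);
}

}  // namespace

// [[Rcpp::export]]
double cpp_log_target(IntegerVector parent, IntegerVector child1,
                      IntegerVector child2, NumericVector time,
                      IntegerMatrix hap, NumericVector freq,
                      NumericVector dist, double theta, double rho,
                      NumericVector theta_prior, NumericVector rho_prior) {
  Chain ch = make_chain(parent, child1, child2, time, hap, freq, dist, theta,
                        rho, theta_prior, rho_prior);
  if (ch.theta < ch.th_lo || ch.theta > ch.th_hi || ch.rho <= 0)
    return R_NegInf;
  recompute_all(ch);
  return ch.total;
}

// [[Rcpp::export]]
List cpp_propose(IntegerVector parent, IntegerVector child1,
                 IntegerVector child2, NumericVector time, IntegerMatrix hap,
                 double theta, double rho, int kind, double delta_theta,
                 double delta_rho) {
  NumericVector dummy(0);
  NumericVector th_pr = NumericVector::create(0.0, 1.0);
  NumericVector r_pr = NumericVector::create(1.0, 1.0);
  Chain ch = make_chain(parent, child1, child2, time, hap, dummy, dummy,
                        theta, rho, th_pr, r_pr);
  ch.L = hap.ncol();
  Prop pr;
  switch (kind) {
    case 1: propose_theta(ch, delta_theta, pr); break;
    case 2: propose_rho(ch, delta_rho, pr); break;
    case 3:
      if (ch.L < 1) stop("internal-haplotype proposal needs at least one SNP");
      propose_flip(ch, pr);
      break;
    case 4: propose_local(ch, pr); break;
    case 5: propose_spr(ch, pr); break;
    default: stop("unknown proposal kind");
  }
  List st = state_of(ch, ch.L);
  st["log_q_forward"] = pr.lqf;
  st["log_q_reverse"] = pr.lqr;
  return st;
}

// [[Rcpp::export]]
List cpp_run_chain(IntegerVector parent, IntegerVector child1,
                   IntegerVector child2, NumericVector time, IntegerMatrix hap,
                   NumericVector freq, NumericVector dist, double theta0,
                   double rho0, NumericVector theta_prior,
                   NumericVector rho_prior, NumericVector probs,
                   double delta_theta, double delta_rho, int n_iter,
                   int burn_in, int thin) {
  Chain ch = make_chain(parent, child1, child2, time, hap, freq, dist, theta0,
                        rho0, theta_prior, rho_prior);
  recompute_all(ch);
  if (!R_finite(ch.total)) stop("initial state has zero posterior density");

  int n_save = (n_iter - burn_in) / thin;
  NumericVector out_theta(n_save), out_rho(n_save), out_tmrca(n_save);
  IntegerMatrix out_parent(ch.m, n_save);
  NumericMatrix out_time(ch.m, n_save);
  IntegerVector attempts(5), accepts(5);
  std::vector<double> cum(5);
  double acc = 0.0;
  for (int i = 0; i < 5; i++) { acc += probs[i]; cum[i] = acc; }

  std::vector<int> sp, sc1, sc2;  // topology snapshots
  std::vector<double> stime;
  std::vector<double> cand_chainS(ch.L), cand_rootchain(ch.L),
      cand_freqS(ch.L);
  std::vector<int> upd_idx;
  std::vector<double> upd_val;
  int saved = 0;

  for (int iter = 1; iter <= n_iter; iter++) {
    double u = unif_rand() * cum[4];
    int kind = 0;
    while (kind < 4 && u > cum[kind]) kind++;
    attempts[kind]++;

    Prop pr;
    double old_theta = ch.theta, old_rho = ch.rho;
    int old_root = ch.root;
    bool topo_kind = (kind == 3 || kind == 4);
    if (topo_kind) {
      sp = ch.parent; sc1 = ch.c1; sc2 = ch.c2; stime = ch.time;
    }
    switch (kind) {
      case 0: propose_theta(ch, delta_theta, pr); break;
      case 1: propose_rho(ch, delta_rho, pr); break;
      case 2: propose_flip(ch, pr); break;
      case 3: propose_local(ch, pr); break;
      case 4: propose_spr(ch, pr); break;
    }

    double cand_ratepr = (kind <= 1) ? rate_lp_of(ch) : ch.ratepr;
    bool reject_hard = !R_finite(cand_ratepr);
    double cand_total = R_NegInf;
    double cand_coal = ch.coal;
    double cand_ttot = ch.ttot;
    upd_idx.clear();
    upd_val.clear();
    cand_chainS = ch.chainS;
    cand_rootchain = ch.rootchain;
    cand_freqS = ch.freqS;

    if (!reject_hard) {
      if (pr.topo) {
        cand_coal = coal_lp_of(ch);
        cand_ttot = total_branch_length(ch);
      }
      if (pr.all_dirty) {
        for (int j = 0; j < ch.L; j++) {
          for (int v2 = 0; v2 < ch.m; v2++) {
            if (v2 == ch.root) continue;
            double nv = chain_term(ch, v2, j, ch.theta);
            upd_idx.push_back(v2 + ch.m * j);
            upd_val.push_back(nv);
            cand_chainS[j] += nv - ch.chain_bm[v2 + ch.m * j];
          }
        }
      } else if (!pr.dirty.empty() || ch.root != old_root ||
                 pr.flip_u >= 0) {
        std::sort(pr.dirty.begin(), pr.dirty.end());
        pr.dirty.erase(std::unique(pr.dirty.begin(), pr.dirty.end()),
                       pr.dirty.end());
        if (pr.flip_u >= 0) {
          // single-marker update
          int j = pr.flip_j;
          for (int v2 : pr.dirty) {
            double nv = (v2 == ch.root) ? 0.0
                                        : chain_term(ch, v2, j, ch.theta);
            upd_idx.push_back(v2 + ch.m * j);
            upd_val.push_back(nv);
            cand_chainS[j] += nv - ch.chain_bm[v2 + ch.m * j];
          }
          // flipped node's frequency term (unlinked explanation)
          int fu = pr.flip_u;
          double newf = freq_term(ch, fu, j);
          cand_freqS[j] += newf - (ch.hap[fu + ch.m * j]
                                       ? std::log(1.0 - ch.freq[j])
                                       : std::log(ch.freq[j]));
          if (fu == ch.root) cand_rootchain[j] = newf;
        } else {
          for (int j = 0; j < ch.L; j++) {
            for (int v2 : pr.dirty) {
              double nv = (v2 == ch.root) ? 0.0
                                          : chain_term(ch, v2, j, ch.theta);
              upd_idx.push_back(v2 + ch.m * j);
              upd_val.push_back(nv);
              cand_chainS[j] += nv - ch.chain_bm[v2 + ch.m * j];
            }
            if (ch.root != old_root) {
              cand_rootchain[j] = freq_term(ch, ch.root, j);
            }
          }
        }
      }
      double dll = data_ll_of(ch, ch.rho, cand_chainS, cand_rootchain,
                              cand_freqS, cand_ttot);
      cand_total = cand_coal + cand_ratepr + dll;
    }

    double log_alpha = cand_total - ch.total + pr.lqr - pr.lqf;
    bool accept = !reject_hard && R_finite(cand_total) &&
                  (log_alpha >= 0 || std::log(unif_rand()) < log_alpha);
    if (accept) {
      accepts[kind]++;
      for (size_t t = 0; t < upd_idx.size(); t++)
        ch.chain_bm[upd_idx[t]] = upd_val[t];
      ch.chainS.swap(cand_chainS);
      ch.rootchain.swap(cand_rootchain);
      ch.freqS.swap(cand_freqS);
      ch.coal = cand_coal;
      ch.ratepr = cand_ratepr;
      ch.ttot = cand_ttot;
      ch.total = cand_total;
    } else {
      ch.theta = old_theta;
      ch.rho = old_rho;
      if (pr.flip_u >= 0)
        ch.hap[pr.flip_u + ch.m * pr.flip_j] =
            1 - ch.hap[pr.flip_u + ch.m * pr.flip_j];
      if (topo_kind) {
        ch.parent = sp; ch.c1 = sc1; ch.c2 = sc2; ch.time = stime;
        ch.root = old_root;
      }
    }

    if (iter % 50000 == 0) recompute_all(ch);  // guard against drift

    if (iter > burn_in && (iter - burn_in) % thin == 0 && saved < n_save) {
      out_theta[saved] = ch.theta;
      out_rho[saved] = ch.rho;
      out_tmrca[saved] = ch.time[ch.root];
      for (int v2 = 0; v2 < ch.m; v2++) {
        out_parent(v2, saved) = ch.parent[v2];
        out_time(v2, saved) = ch.time[v2];
      }
      saved++;
    }
  }

  double inc_total = ch.total;
  recompute_all(ch);
  return List::create(
      _["theta"] = out_theta, _["rho"] = out_rho, _["tmrca"] = out_tmrca,
      _["parent"] = out_parent, _["time"] = out_time,
      _["attempts"] = attempts, _["accepts"] = accepts,
      _["final_state"] = state_of(ch, ch.L), _["final_total"] = ch.total,
      _["incremental_total"] = inc_total);
}
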