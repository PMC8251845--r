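#include <Rcpp.h>
#include <algorithm>
#include <vector>

// Greedy 1:1 without-replacement matching over PS-sorted controls.
//
// Controls live in a Fenwick (binary indexed) tree keyed by their position
// in the PS-sorted order, holding 1 while unmatched. Range counts, k-th
// unmatched selection and deletion are all O(log n), so eligible-control
// lookup beats a linear scan per treated subject while remaining
// bit-identical to the naive reference (same RNG draws in the same order).
//
// All randomness comes from R's RNG stream (unif_rand), so a set.seed()
// in the calling R code makes results reproducible, and a pure-R
// re-implementation consuming the same draws reproduces them exactly.

namespace {

class Fenwick {
public:
  explicit Fenwick(int n) : n_(n), tree_(n + 1, 0) {
    for (int i = 1; i <= n_; ++i) {
      tree_[i] += 1;
      int j = i + (i & -i);
      if (j <= n_) tree_[j] += tree_[i];
    }
    log_ = 1;
    while ((1 << log_) <= n_) ++log_;
  }

  // count of unmatched controls with sorted position < i (prefix [0, i))
  int prefix(int i) const {
    int s = 0;
    for (; i > 0; i -= i & -i) s += tree_[i];
    return s;
  }

  int count(int lo, int hi) const {  // [lo, hi)
    if (hi <= lo) return 0;
    return prefix(hi) - prefix(lo);
  }

  // 0-based sorted position of the k-th (1-based) unmatched control
  int select(int k) const {
    int pos = 0;
    for (int pw = 1 << log_; pw > 0; pw >>= 1) {
      if (pos + pw <= n_ && tree_[pos + pw] < k) {
        pos += pw;
        k -= tree_[pos];
      }
    }
    return pos;  // tree is 1-based; pos is the 0-based index
  }

  void remove(int i) {  // 0-based
    for (int j = i + 1; j <= n_; j += j & -j) tree_[j] -= 1;
  }

private:
  int n_, log_;
  std::vector<int> tree_;
};

// uniform integer in 1..k from R's stream, matching floor(runif(1) * k) + 1
inline int runif_int(int k) {
  int r = static_cast<int>(unif_rand() * k) + 1;
  return r > k ? k : r;
}

}  // namespace

// [[Rcpp::export(name = ".match_core")]]
Rcpp::IntegerVector match_core(Rcpp::NumericVector ps_treated,
                               Rcpp::NumericVector ps_control,
                               double caliper, bool nearest) {
  const int nt = ps_treated.size();
  const int nc = ps_control.size();
  const double* pc = ps_control.begin();
  Rcpp::IntegerVector out(nt, 0);  // 1-based sorted control index, 0 = none
  if (nc == 0) return out;
  Fenwick fw(nc);
  int remaining = nc;

  for (int i = 0; i < nt && remaining > 0; ++i) {
    const double pt = ps_treated[i];

    if (!nearest) {
      // caliper-random: uniform draw among unmatched controls in the window
      const int lo = std::lower_bound(pc, pc + nc, pt - caliper) - pc;
      const int hi = std::upper_bound(pc, pc + nc, pt + caliper) - pc;
      const int before = fw.prefix(lo);
      const int cnt = fw.prefix(hi) - before;
      if (cnt == 0) continue;
      const int idx = fw.select(before + runif_int(cnt));
      out[i] = idx + 1;
      fw.remove(idx);
      --remaining;
      continue;
    }

    // nearest neighbor within caliper; exact-distance ties broken uniformly
    const int pos = std::lower_bound(pc, pc + nc, pt) - pc;
    const int before = fw.prefix(pos);
    const int left = (before >= 1) ? fw.select(before) : -1;
    const int right = (remaining - before >= 1) ? fw.select(before + 1) : -1;
    const double dl = (left >= 0) ? pt - pc[left] : R_PosInf;
    const double dr = (right >= 0) ? pc[right] - pt : R_PosInf;
    const double d = dl < dr ? dl : dr;
    if (!(d <= caliper)) continue;

    int l1 = 0, cl = 0, r1 = 0, cr = 0;
    if (dl == d) {  // left-side candidates share the value pc[left] < pt
      const double* a = std::lower_bound(pc, pc + nc, pc[left]);
      const double* b = std::upper_bound(pc, pc + nc, pc[left]);
      l1 = a - pc;
      cl = fw.count(l1, b - pc);
    }
    if (dr == d) {  // right-side candidates share the value pc[right] >= pt
      const double* a = std::lower_bound(pc, pc + nc, pc[right]);
      const double* b = std::upper_bound(pc, pc + nc, pc[right]);
      r1 = a - pc;
      cr = fw.count(r1, b - pc);
    }
    const int total = cl + cr;
    const int m = (total == 1) ? 1 : runif_int(total);
    const int idx = (m <= cl) ? fw.select(fw.prefix(l1) + m)
                              : fw.select(fw.prefix(r1) + (m - cl));
    out[i] = idx + 1;
    fw.remove(idx);
    --remaining;
  }
  return out;
}
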