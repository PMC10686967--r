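// Compiled kernels for the ALE pipeline: modeled-activation placement,
// analytic voxel-null construction by histogram convolution in (1 - MA)
// space, the Monte-Carlo max-statistic null, and 3-D connected components.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static std::vector<std::array<int, 3> > conn_offsets(int conn) {
  if (conn != 6 && conn != 18 && conn != 26)
    stop("unknown connectivity (must be 6, 18 or 26)");
  std::vector<std::array<int, 3> > off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        std::array<int, 3> o = {{dx, dy, dz}};
        off.push_back(o);
      }
  return off;
}

struct UnionFind {
  std::vector<int> parent;
  explicit UnionFind(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }
};

// Place one experiment's foci kernels (voxelwise maximum) into `ma`,
// recording first-touched mask rows in `touched`.
static void place_foci(std::vector<double>& ma, std::vector<int>& touched,
                       const int* dim, const int* lookup,
                       const int* fx, const int* fy, const int* fz, int n_foci,
                       const int* ox, const int* oy, const int* oz,
                       const double* val, int n_off) {
  for (int f = 0; f < n_foci; ++f) {
    const int cx = fx[f], cy = fy[f], cz = fz[f];
    for (int m = 0; m < n_off; ++m) {
      const int i = cx + ox[m], j = cy + oy[m], k = cz + oz[m];
      if (i < 0 || j < 0 || k < 0 || i >= dim[0] || j >= dim[1] || k >= dim[2])
        continue;
      const int mi = lookup[i + dim[0] * (j + dim[1] * (long long)k)];
      if (mi < 0) continue;
      if (ma[mi] == 0.0) touched.push_back(mi);
      if (val[m] > ma[mi]) ma[mi] = val[m];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_ma_matrix(IntegerVector dim, IntegerVector lookup,
                            int n_mask, List foci_list, List kernel_list) {
  const int K = foci_list.size();
  NumericMatrix out(n_mask, K);
  std::vector<double> ma(n_mask, 0.0);
  std::vector<int> touched;
  for (int e = 0; e < K; ++e) {
    IntegerMatrix foci = foci_list[e];      // F x 3, 0-based voxel coords
    List kern = kernel_list[e];
    IntegerMatrix off = kern["offsets"];    // M x 3
    NumericVector val = kern["values"];
    touched.clear();
    place_foci(ma, touched, dim.begin(), lookup.begin(),
               &foci(0, 0), &foci(0, 1), &foci(0, 2), foci.nrow(),
               &off(0, 0), &off(0, 1), &off(0, 2), val.begin(), off.nrow());
    for (size_t t = 0; t < touched.size(); ++t) {
      out(touched[t], e) = ma[touched[t]];
      ma[touched[t]] = 0.0;
    }
  }
  return out;
}

// Null distribution of the ALE score under independent spatial relocation of
// each experiment: sequential convolution of the per-experiment MA-value
// histograms through ALE = 1 - prod(1 - MA), on a fixed grid of bins of
// width `bin_width` (left-edge representative values, conservative).
// [[Rcpp::export]]
NumericVector cpp_voxel_null(NumericMatrix ma, double bin_width) {
  if (bin_width <= 0) stop("bin width must be > 0");
  const int V = ma.nrow(), K = ma.ncol();
  if (V < 1 || K < 1) stop("need at least one experiment and one voxel");
  const int nbins = (int)std::ceil(1.0 / bin_width) + 2;
  std::vector<double> cur(nbins, 0.0), nxt(nbins, 0.0), mh(nbins, 0.0);
  std::vector<int> mb;
  cur[0] = 1.0;
  int cur_max = 0;
  for (int e = 0; e < K; ++e) {
    double m0 = 0.0;
    mb.clear();
    for (int v = 0; v < V; ++v) {
      int b = (int)(ma(v, e) / bin_width + 1e-9);
      if (b >= nbins) b = nbins - 1;
      if (b == 0) m0 += 1.0;
      else { if (mh[b] == 0.0) mb.push_back(b); mh[b] += 1.0; }
    }
    m0 /= V;
    std::sort(mb.begin(), mb.end());
    std::fill(nxt.begin(), nxt.end(), 0.0);
    int new_max = 0;
    for (int a = 0; a <= cur_max; ++a) {
      const double pa = cur[a];
      if (pa <= 0.0) continue;
      const double oma = 1.0 - a * bin_width;
      if (m0 > 0.0) { nxt[a] += pa * m0; if (a > new_max) new_max = a; }
      for (size_t ib = 0; ib < mb.size(); ++ib) {
        const int bi = mb[ib];
        const double vnew = 1.0 - oma * (1.0 - bi * bin_width);
        int nb = (int)(vnew / bin_width + 1e-9);
        if (nb >= nbins) nb = nbins - 1;
        nxt[nb] += pa * (mh[bi] / V);
        if (nb > new_max) new_max = nb;
      }
    }
    std::swap(cur, nxt);
    cur_max = new_max;
    for (size_t ib = 0; ib < mb.size(); ++ib) mh[mb[ib]] = 0.0;
  }
  return NumericVector(cur.begin(), cur.begin() + cur_max + 1);
}

// Connected components among the given 0-based voxel coordinates.
// Returns 1-based component labels in order of first appearance.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerMatrix vox, IntegerVector dim,
                                   int conn) {
  const std::vector<std::array<int, 3> > offs = conn_offsets(conn);
  const int S = vox.nrow();
  IntegerVector labels(S);
  if (S == 0) return labels;
  std::map<long long, int> where;
  for (int s = 0; s < S; ++s) {
    long long li = vox(s, 0) + dim[0] * (vox(s, 1) + dim[1] * (long long)vox(s, 2));
    where[li] = s;
  }
  UnionFind uf(S);
  for (int s = 0; s < S; ++s) {
    for (size_t m = 0; m < offs.size(); ++m) {
      const int i = vox(s, 0) + offs[m][0];
      const int j = vox(s, 1) + offs[m][1];
      const int k = vox(s, 2) + offs[m][2];
      if (i < 0 || j < 0 || k < 0 || i >= dim[0] || j >= dim[1] || k >= dim[2])
        continue;
      std::map<long long, int>::iterator it =
        where.find(i + dim[0] * (j + dim[1] * (long long)k));
      if (it != where.end()) uf.unite(s, it->second);
    }
  }
  std::map<int, int> relabel;
  int next = 0;
  for (int s = 0; s < S; ++s) {
    int r = uf.find(s);
    if (relabel.find(r) == relabel.end()) relabel[r] = ++next;
    labels[s] = relabel[r];
  }
  return labels;
}

// Monte-Carlo max-statistic null: per iteration, every experiment's foci are
// redrawn uniformly over the mask, the ALE map recomputed, and the maximum
// ALE value and the maximum size of connected components with ALE strictly
// above `cf_cutoff` recorded. Uses R's RNG (reproducible under set.seed).
// [[Rcpp::export]]
NumericMatrix cpp_max_stat_null(IntegerVector dim, IntegerMatrix mask_vox,
                                IntegerVector lookup, List kernel_list,
                                IntegerVector foci_counts, int n_iter,
                                double cf_cutoff, int conn) {
  if (n_iter < 1) stop("iterations must be >= 1");
  const std::vector<std::array<int, 3> > offs = conn_offsets(conn);
  const int V = mask_vox.nrow();
  const int K = foci_counts.size();
  const long long nvox = (long long)dim[0] * dim[1] * dim[2];

  // unpack kernels once
  std::vector<const int*> kox(K), koy(K), koz(K);
  std::vector<const double*> kval(K);
  std::vector<int> knoff(K);
  std::vector<IntegerMatrix> koff_keep(K);
  std::vector<NumericVector> kval_keep(K);
  for (int e = 0; e < K; ++e) {
    List kern = kernel_list[e];
    koff_keep[e] = as<IntegerMatrix>(kern["offsets"]);
    kval_keep[e] = as<NumericVector>(kern["values"]);
    kox[e] = &koff_keep[e](0, 0);
    koy[e] = &koff_keep[e](0, 1);
    koz[e] = &koff_keep[e](0, 2);
    kval[e] = kval_keep[e].begin();
    knoff[e] = koff_keep[e].nrow();
  }

  std::vector<double> ma(V, 0.0), prod(V, 1.0);
  std::vector<int> touched, dirty_list, fi(64);
  std::vector<unsigned char> dirty(V, 0);
  std::vector<int> slab(nvox, -1);
  NumericMatrix out(n_iter, 2);

  for (int it = 0; it < n_iter; ++it) {
    dirty_list.clear();
    for (int e = 0; e < K; ++e) {
      const int nf = foci_counts[e];
      std::vector<int> fx(nf), fy(nf), fz(nf);
      for (int f = 0; f < nf; ++f) {
        int v = (int)(unif_rand() * V);
        if (v >= V) v = V - 1;
        fx[f] = mask_vox(v, 0); fy[f] = mask_vox(v, 1); fz[f] = mask_vox(v, 2);
      }
      touched.clear();
      place_foci(ma, touched, dim.begin(), lookup.begin(),
                 &fx[0], &fy[0], &fz[0], nf,
                 kox[e], koy[e], koz[e], kval[e], knoff[e]);
      for (size_t t = 0; t < touched.size(); ++t) {
        const int mi = touched[t];
        if (!dirty[mi]) { dirty[mi] = 1; dirty_list.push_back(mi); }
        prod[mi] *= (1.0 - ma[mi]);
        ma[mi] = 0.0;
      }
    }
    // max ALE and suprathreshold set over dirty voxels (others have ALE 0)
    double max_ale = 0.0;
    std::vector<int> supra;
    for (size_t t = 0; t < dirty_list.size(); ++t) {
      const int mi = dirty_list[t];
      const double ale = 1.0 - prod[mi];
      if (ale > max_ale) max_ale = ale;
      if (ale > cf_cutoff) supra.push_back(mi);
      prod[mi] = 1.0;
      dirty[mi] = 0;
    }
    int max_size = 0;
    if (!supra.empty()) {
      const int S = (int)supra.size();
      for (int s = 0; s < S; ++s) {
        const int mi = supra[s];
        slab[mask_vox(mi, 0) + dim[0] * (mask_vox(mi, 1) + dim[1] * (long long)mask_vox(mi, 2))] = s;
      }
      UnionFind uf(S);
      for (int s = 0; s < S; ++s) {
        const int mi = supra[s];
        for (size_t m = 0; m < offs.size(); ++m) {
          const int i = mask_vox(mi, 0) + offs[m][0];
          const int j = mask_vox(mi, 1) + offs[m][1];
          const int k = mask_vox(mi, 2) + offs[m][2];
          if (i < 0 || j < 0 || k < 0 || i >= dim[0] || j >= dim[1] || k >= dim[2])
            continue;
          const int o = slab[i + dim[0] * (j + dim[1] * (long long)k)];
          if (o >= 0) uf.unite(s, o);
        }
      }
      std::vector<int> size(S, 0);
      for (int s = 0; s < S; ++s) ++size[uf.find(s)];
      max_size = *std::max_element(size.begin(), size.end());
      for (int s = 0; s < S; ++s) {
        const int mi = supra[s];
        slab[mask_vox(mi, 0) + dim[0] * (mask_vox(mi, 1) + dim[1] * (long long)mask_vox(mi, 2))] = -1;
      }
    }
    out(it, 0) = max_ale;
    out(it, 1) = max_size;
  }
  return out;
}
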