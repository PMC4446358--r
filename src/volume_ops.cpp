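#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Shared helpers for 2D/3D integer label volumes stored column-major as in R.
// dims has length 2 or 3; face connectivity only (4-nbr in 2D, 6-nbr in 3D).

static inline int n_dims(const IntegerVector& dims) { return dims.size(); }

// Enumerate face neighbours of linear index idx; writes into out, returns count.
static int face_neighbours(R_xlen_t idx, const IntegerVector& dims,
                           R_xlen_t* out) {
    int nd = n_dims(dims);
    int d0 = dims[0];
    int d1 = dims[1];
    int d2 = nd == 3 ? dims[2] : 1;
    R_xlen_t plane = (R_xlen_t)d0 * d1;
    int i0 = (int)(idx % d0);
    int i1 = (int)((idx / d0) % d1);
    int i2 = (int)(idx / plane);
    int n = 0;
    if (i0 > 0)      out[n++] = idx - 1;
    if (i0 < d0 - 1) out[n++] = idx + 1;
    if (i1 > 0)      out[n++] = idx - d0;
    if (i1 < d1 - 1) out[n++] = idx + d0;
    if (nd == 3) {
        if (i2 > 0)      out[n++] = idx - plane;
        if (i2 < d2 - 1) out[n++] = idx + plane;
    }
    return n;
}

//' @useDynLib cadaSeg, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = "cpp_cc_label")]]
IntegerVector cpp_cc_label(LogicalVector mask, IntegerVector dims) {
    R_xlen_t n = mask.size();
    IntegerVector lab(n, 0);
    R_xlen_t nbr[6];
    std::vector<R_xlen_t> stack;
    int next = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s] != 0) continue;
        ++next;
        lab[s] = next;
        stack.clear();
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t cur = stack.back();
            stack.pop_back();
            int k = face_neighbours(cur, dims, nbr);
            for (int j = 0; j < k; ++j) {
                R_xlen_t q = nbr[j];
                if (mask[q] && lab[q] == 0) {
                    lab[q] = next;
                    stack.push_back(q);
                }
            }
        }
    }
    return lab;
}

struct FloodItem {
    double height;
    R_xlen_t order;   // FIFO tie-break: earlier-queued pixels flood first
    R_xlen_t idx;
    int label;
};
struct FloodCmp {
    bool operator()(const FloodItem& a, const FloodItem& b) const {
        if (a.height != b.height) return a.height > b.height;
        return a.order > b.order;
    }
};

// Marker-seeded priority-flood watershed. markers > 0 are seeds; every pixel
// (with region >= 0 matching, see below) receives a marker label, watershed
// "line" pixels are assigned to the basin that reaches them first. If
// `region` is non-empty, flooding never crosses pixels whose region id
// differs (used to carve Voronoi-style fragments inside fixed regions).
// [[Rcpp::export(name = "cpp_watershed")]]
IntegerVector cpp_watershed(NumericVector height, IntegerVector markers,
                            IntegerVector dims, IntegerVector region) {
    R_xlen_t n = height.size();
    bool has_region = region.size() == n;
    IntegerVector lab(n, 0);
    std::priority_queue<FloodItem, std::vector<FloodItem>, FloodCmp> pq;
    R_xlen_t order = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (markers[i] > 0) {
            lab[i] = markers[i];
            pq.push({height[i], order++, i, markers[i]});
        }
    }
    R_xlen_t nbr[6];
    while (!pq.empty()) {
        FloodItem it = pq.top();
        pq.pop();
        int k = face_neighbours(it.idx, dims, nbr);
        for (int j = 0; j < k; ++j) {
            R_xlen_t q = nbr[j];
            if (lab[q] != 0) continue;
            if (has_region && region[q] != region[it.idx]) continue;
            lab[q] = it.label;
            // flood at max(own height, current front): classic priority flood
            double h = height[q] > it.height ? height[q] : it.height;
            pq.push({h, order++, q, it.label});
        }
    }
    return lab;
}

// Adjacent unequal-label pixel pairs under face connectivity. Returns a list
// with integer vectors a, b (labels, a < b), pa, pb (1-based linear pixel
// indices of the two sides). Background label contributes no pairs.
// [[Rcpp::export(name = "cpp_adjacent_pairs")]]
List cpp_adjacent_pairs(IntegerVector labels, IntegerVector dims,
                        int background) {
    R_xlen_t n = labels.size();
    int nd = n_dims(dims);
    int d0 = dims[0];
    int d1 = dims[1];
    R_xlen_t plane = (R_xlen_t)d0 * d1;
    std::vector<int> va, vb;
    std::vector<double> pa, pb;
    R_xlen_t offs[3] = {1, d0, plane};
    int noff = nd == 3 ? 3 : 2;
    for (int o = 0; o < noff; ++o) {
        for (R_xlen_t i = 0; i < n; ++i) {
            // skip wrap-around at the end of the axis
            if (o == 0 && (i % d0) == (R_xlen_t)(d0 - 1)) continue;
            if (o == 1 && ((i / d0) % d1) == (R_xlen_t)(d1 - 1)) continue;
            if (o == 2 && (i / plane) == (R_xlen_t)(dims[2] - 1)) continue;
            R_xlen_t j = i + offs[o];
            int li = labels[i], lj = labels[j];
            if (li == lj || li == background || lj == background) continue;
            if (li < lj) {
                va.push_back(li); vb.push_back(lj);
                pa.push_back((double)(i + 1)); pb.push_back((double)(j + 1));
            } else {
                va.push_back(lj); vb.push_back(li);
                pa.push_back((double)(j + 1)); pb.push_back((double)(i + 1));
            }
        }
    }
    return List::create(_["a"] = wrap(va), _["b"] = wrap(vb),
                        _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}
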