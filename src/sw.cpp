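#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Smith-Waterman local alignment on {A,C,G,T} strings.
// Rows index the read, columns the reference.
//  - "deletion in a read" consumes reference only (move left, penalty gap_del)
//  - "insertion in a read" consumes read only (move up, penalty gap_ins)
// Tie-breaking is deterministic: diagonal > up (insertion) > left (deletion),
// and the best cell is the first maximum in row-major (read-position) order.

static inline int base_score(char a, char b, int match, int mismatch) {
  return (a == b) ? match : mismatch;
}

// Among score-optimal local alignments the traceback prefers the path with
// the most diagonal (match/mismatch) columns, then per-cell diagonal > up
// (insertion) > left (deletion). A mismatch (-2) ties a deletion+insertion
// pair (-1 - 1) under the default scoring, and without the path-level rule a
// true substitution can be reported as a spurious gap pair.
// [[Rcpp::export]]
List sw_align_cpp(std::string read, std::string ref,
                  int match, int mismatch, int gap_del, int gap_ins) {
  const int n = read.size(), m = ref.size();
  // H: score; G: max diagonal steps among score-optimal paths into the cell
  std::vector<int> H((n + 1) * (m + 1), 0), G((n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0, bg = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int diag = H[(i - 1) * (m + 1) + (j - 1)] +
        base_score(read[i - 1], ref[j - 1], match, mismatch);
      const int up   = H[(i - 1) * (m + 1) + j] + gap_ins;
      const int left = H[i * (m + 1) + (j - 1)] + gap_del;
      int h = diag;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      int g = 0;
      if (h > 0) {
        g = -1;
        if (diag == h) g = std::max(g, G[(i - 1) * (m + 1) + (j - 1)] + 1);
        if (up == h) g = std::max(g, G[(i - 1) * (m + 1) + j]);
        if (left == h) g = std::max(g, G[i * (m + 1) + (j - 1)]);
      }
      H[i * (m + 1) + j] = h;
      G[i * (m + 1) + j] = g;
      if (h > best || (h == best && h > 0 && g > bg)) {
        best = h; bi = i; bj = j; bg = g;
      }
    }
  }
  std::string ops;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && H[i * (m + 1) + j] > 0) {
    const int h = H[i * (m + 1) + j];
    const int g = G[i * (m + 1) + j];
    const int diag = H[(i - 1) * (m + 1) + (j - 1)] +
      base_score(read[i - 1], ref[j - 1], match, mismatch);
    if (h == diag && G[(i - 1) * (m + 1) + (j - 1)] + 1 == g) {
      ops.push_back(read[i - 1] == ref[j - 1] ? '=' : 'X');
      --i; --j;
    } else if (h == H[(i - 1) * (m + 1) + j] + gap_ins &&
               G[(i - 1) * (m + 1) + j] == g) {
      ops.push_back('I');
      --i;
    } else {
      ops.push_back('D');
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // 0-based half-open spans
  return List::create(
    _["score"] = best,
    _["read_start"] = i, _["read_end"] = bi,
    _["ref_start"] = j, _["ref_end"] = bj,
    _["ops"] = ops);
}

static int sw_score_one(const char *read, int n, const char *ref, int m,
                        int match, int mismatch, int gap_del, int gap_ins,
                        std::vector<int> &prev, std::vector<int> &cur) {
  prev.assign(m + 1, 0);
  cur.assign(m + 1, 0);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      int h = prev[j - 1] + base_score(read[i - 1], ref[j - 1], match, mismatch);
      const int up = prev[j] + gap_ins;
      const int left = cur[j - 1] + gap_del;
      if (up > h) h = up;
      if (left > h) h = left;
      if (h < 0) h = 0;
      cur[j] = h;
      if (h > best) best = h;
    }
    std::swap(prev, cur);
  }
  return best;
}

// Score matrix for many reads against many references (no traceback).
// [[Rcpp::export]]
IntegerMatrix sw_score_matrix_cpp(CharacterVector reads, CharacterVector refs,
                                  int match, int mismatch,
                                  int gap_del, int gap_ins) {
  const int nr = reads.size(), nf = refs.size();
  IntegerMatrix out(nr, nf);
  std::vector<int> prev, cur;
  std::vector<std::string> refstr(nf);
  for (int k = 0; k < nf; ++k) refstr[k] = as<std::string>(refs[k]);
  for (int r = 0; r < nr; ++r) {
    const std::string rd = as<std::string>(reads[r]);
    for (int k = 0; k < nf; ++k) {
      out(r, k) = sw_score_one(rd.c_str(), rd.size(),
                               refstr[k].c_str(), refstr[k].size(),
                               match, mismatch, gap_del, gap_ins, prev, cur);
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask (two-pass union-find).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  auto find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };
  int next_label = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      int neigh[4]; int nn = 0;
      if (i > 0 && mask(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0) {
        if (mask(i, j - 1)) neigh[nn++] = lab(i, j - 1);
        if (i > 0 && mask(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (i < nr - 1 && mask(i + 1, j - 1)) neigh[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        ++next_label;
        parent.push_back(next_label);
        lab(i, j) = next_label;
      } else {
        int mn = neigh[0];
        for (int k = 1; k < nn; ++k) mn = std::min(mn, neigh[k]);
        lab(i, j) = mn;
        for (int k = 0; k < nn; ++k) unite(mn, neigh[k]);
      }
    }
  }
  // second pass: flatten labels to 1..K
  std::vector<int> remap(next_label + 1, 0);
  int K = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      const int r = find(lab(i, j));
      if (!remap[r]) remap[r] = ++K;
      lab(i, j) = remap[r];
    }
  }
  return lab;
}

// Separable Gaussian blur with reflective boundaries.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix img, double sigma) {
  const int nr = img.nrow(), nc = img.ncol();
  const int h = std::max(1, (int) std::ceil(3.0 * sigma));
  std::vector<double> k(2 * h + 1);
  double s = 0;
  for (int d = -h; d <= h; ++d) {
    k[d + h] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += k[d + h];
  }
  for (double &v : k) v /= s;
  auto reflect = [](int x, int n) {
    while (x < 0 || x >= n) { if (x < 0) x = -x - 1; if (x >= n) x = 2 * n - x - 1; }
    return x;
  };
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = 0;
      for (int d = -h; d <= h; ++d) v += k[d + h] * img(reflect(i + d, nr), j);
      tmp(i, j) = v;
    }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double v = 0;
      for (int d = -h; d <= h; ++d) v += k[d + h] * tmp(i, reflect(j + d, nc));
      out(i, j) = v;
    }
  return out;
}

// Weighted per-position pileup over {A,C,G,T,del} from alignment op strings.
// ref_start is 0-based; ops use =/X (consume both), D (ref only), I (read only).
// edge_mask drops the first/last k reference-consuming columns of each
// alignment (local alignment selectively excludes errors at its ends, so
// rate estimation uses interior columns only; consensus uses edge_mask = 0).
// [[Rcpp::export]]
List pileup_cpp(CharacterVector ops, IntegerVector ref_start,
                CharacterVector read, IntegerVector read_start,
                NumericVector weight, int ref_len, int edge_mask = 0) {
  NumericMatrix tally(ref_len, 5); // A C G T del
  double insertions = 0, aligned_bases = 0;
  const int n = ops.size();
  for (int r = 0; r < n; ++r) {
    const std::string op = as<std::string>(ops[r]);
    const std::string rd = as<std::string>(read[r]);
    int rp = ref_start[r], qp = read_start[r];
    const double w = weight[r];
    int n_refcols = 0;
    for (size_t t = 0; t < op.size(); ++t)
      if (op[t] != 'I') ++n_refcols;
    int refcol = -1;
    for (size_t t = 0; t < op.size(); ++t) {
      const char c = op[t];
      if (c != 'I') ++refcol;
      const bool masked = (c != 'I') &&
        (refcol < edge_mask || refcol >= n_refcols - edge_mask);
      if (masked) {
        if (c == '=' || c == 'X') { ++rp; ++qp; }
        else if (c == 'D') ++rp;
        continue;
      }
      if (c == '=' || c == 'X') {
        if (rp >= 0 && rp < ref_len) {
          int col;
          switch (rd[qp]) {
            case 'A': col = 0; break;
            case 'C': col = 1; break;
            case 'G': col = 2; break;
            case 'T': col = 3; break;
            default: col = -1;
          }
          if (col >= 0) tally(rp, col) += w;
        }
        ++rp; ++qp; aligned_bases += w;
      } else if (c == 'D') {
        if (rp >= 0 && rp < ref_len) tally(rp, 4) += w;
        ++rp;
      } else if (c == 'I') {
        ++qp; insertions += w; aligned_bases += w;
      }
    }
  }
  return List::create(_["tally"] = tally, _["insertions"] = insertions,
                      _["aligned_bases"] = aligned_bases);
}
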