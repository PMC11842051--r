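// Edit-distance alignment kernels: adaptive banded global alignment with an
// optional transcript, fitting alignment (free end gaps on the longer
// sequence), unique-anchor matching for chromosome-scale colinear alignment,
// and the dot-plot scan.

#include <Rcpp.h>
#include <cstdint>
#include <limits>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const int BIG = std::numeric_limits<int>::max() / 4;

// Banded global edit distance between a and b with diagonal slack h.
// If make_transcript, also fills ops with one char per alignment column
// ('=', 'X', 'D' consumes a only, 'I' consumes b only), using the
// tie-break match > mismatch > delete > insert.
static int band_dp(const std::string& a, const std::string& b, int h,
                   bool make_transcript, std::string* ops) {
  int la = (int)a.size(), lb = (int)b.size();
  int lo = std::min(0, lb - la) - h;
  int hi = std::max(0, lb - la) + h;
  int W = hi - lo + 1;
  std::vector<int> prev(W, BIG), cur(W, BIG);
  std::vector<uint8_t> tb;
  if (make_transcript) tb.assign((size_t)(la + 1) * W, 0); // 1=diag,2=up(D),3=left(I)
  // row 0
  for (int d = lo; d <= hi; ++d) {
    int j = d; // i = 0
    if (j >= 0 && j <= lb) {
      prev[d - lo] = j;
      if (make_transcript && j > 0) tb[d - lo] = 3;
    }
  }
  for (int i = 1; i <= la; ++i) {
    for (int d = lo; d <= hi; ++d) cur[d - lo] = BIG;
    for (int d = lo; d <= hi; ++d) {
      int j = i + d;
      if (j < 0 || j > lb) continue;
      int best = BIG;
      uint8_t dir = 0;
      if (j > 0) { // diagonal from (i-1, j-1): same d
        int c = prev[d - lo];
        if (c < BIG) {
          int cost = c + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (cost < best) { best = cost; dir = 1; }
        }
      }
      { // up from (i-1, j): d+1 in prev
        if (d + 1 <= hi) {
          int c = prev[d + 1 - lo];
          if (c < BIG && c + 1 < best) { best = c + 1; dir = 2; }
        }
      }
      { // left from (i, j-1): d-1 in cur
        if (d - 1 >= lo) {
          int c = cur[d - 1 - lo];
          if (c < BIG && c + 1 < best) { best = c + 1; dir = 3; }
        }
      }
      cur[d - lo] = best;
      if (make_transcript) tb[(size_t)i * W + (d - lo)] = dir;
    }
    std::swap(prev, cur);
  }
  int dres = lb - la;
  int res = (dres >= lo && dres <= hi) ? prev[dres - lo] : BIG;
  if (make_transcript && ops && res < BIG) {
    ops->clear();
    int i = la, j = lb;
    while (i > 0 || j > 0) {
      uint8_t dir = (i == 0) ? 3 : tb[(size_t)i * W + (j - i - lo)];
      if (dir == 1) {
        ops->push_back(a[i - 1] == b[j - 1] ? '=' : 'X');
        --i; --j;
      } else if (dir == 2) {
        ops->push_back('D');
        --i;
      } else {
        ops->push_back('I');
        --j;
      }
    }
    std::reverse(ops->begin(), ops->end());
  }
  return res;
}

static int adaptive_band(const std::string& a, const std::string& b,
                         bool make_transcript, std::string* ops) {
  if (a.empty()) {
    if (ops) ops->assign(b.size(), 'I');
    return (int)b.size();
  }
  if (b.empty()) {
    if (ops) ops->assign(a.size(), 'D');
    return (int)a.size();
  }
  int h = 16;
  int maxlen = (int)std::max(a.size(), b.size());
  while (true) {
    int d = band_dp(a, b, h, make_transcript, ops);
    if (d <= h || h >= maxlen) return d;
    h *= 2;
  }
}

// (myers_bounded is defined below; declared here for use)
static int myers_bounded(const std::string& a, const std::string& b,
                         int bound);

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  return myers_bounded(a, b, (int)std::max(a.size(), b.size()));
}

// [[Rcpp::export]]
List cpp_align_global(std::string a, std::string b) {
  std::string ops;
  int d = adaptive_band(a, b, true, &ops);
  return List::create(_["distance"] = d, _["ops"] = ops);
}

// Fitting alignment: align all of q against the best-matching substring of
// t (free gaps at both ends of t). Returns the 0-based half-open interval of
// t covered by the core and the edit distance of the fit.
// [[Rcpp::export]]
List cpp_fitting_align(std::string q, std::string t) {
  int lq = (int)q.size(), lt = (int)t.size();
  std::vector<int> prev(lt + 1), cur(lt + 1);
  std::vector<int> pstart(lt + 1), cstart(lt + 1);
  for (int j = 0; j <= lt; ++j) { prev[j] = 0; pstart[j] = j; }
  for (int i = 1; i <= lq; ++i) {
    cur[0] = i; cstart[0] = 0;
    for (int j = 1; j <= lt; ++j) {
      int diag = prev[j - 1] + (q[i - 1] == t[j - 1] ? 0 : 1);
      int up = prev[j] + 1;   // consume q
      int left = cur[j - 1] + 1; // consume t
      int best = diag; int src = 0;
      if (up < best) { best = up; src = 1; }
      if (left < best) { best = left; src = 2; }
      cur[j] = best;
      cstart[j] = (src == 0) ? pstart[j - 1] : (src == 1 ? pstart[j] : cstart[j - 1]);
    }
    std::swap(prev, cur);
    std::swap(pstart, cstart);
  }
  int bj = 0, bd = BIG;
  for (int j = 0; j <= lt; ++j)
    if (prev[j] < bd) { bd = prev[j]; bj = j; }
  return List::create(_["start"] = pstart[bj], _["end"] = bj,
                      _["distance"] = bd);
}

static const uint64_t HB = 1099511628211ULL;

static std::vector<uint64_t> kmer_hashes(const std::string& s, int w) {
  std::vector<uint64_t> out;
  int L = (int)s.size();
  if (L < w) return out;
  uint64_t pw = 1;
  for (int i = 0; i < w; ++i) pw *= HB;
  uint64_t h = 0;
  for (int i = 0; i < w; ++i) h = h * HB + (uint64_t)(unsigned char)s[i];
  out.reserve(L - w + 1);
  out.push_back(h);
  for (int i = w; i < L; ++i) {
    h = h * HB + (uint64_t)(unsigned char)s[i] -
        pw * (uint64_t)(unsigned char)s[i - w];
    out.push_back(h);
  }
  return out;
}

// Positions (0-based) of w-mers that occur exactly once in a, exactly once
// in b, and are equal; sorted by position in a.
// [[Rcpp::export]]
DataFrame cpp_anchor_matches(std::string a, std::string b, int w) {
  std::vector<uint64_t> ha = kmer_hashes(a, w), hb = kmer_hashes(b, w);
  std::unordered_map<uint64_t, int> pa, pb; // pos or -2 if repeated
  for (size_t i = 0; i < ha.size(); ++i) {
    auto it = pa.find(ha[i]);
    if (it == pa.end()) pa.emplace(ha[i], (int)i);
    else it->second = -2;
  }
  for (size_t i = 0; i < hb.size(); ++i) {
    auto it = pb.find(hb[i]);
    if (it == pb.end()) pb.emplace(hb[i], (int)i);
    else it->second = -2;
  }
  std::vector<int> xa, xb;
  for (size_t i = 0; i < ha.size(); ++i) {
    auto it = pa.find(ha[i]);
    if (it->second != (int)i) continue; // repeated in a
    auto jb = pb.find(ha[i]);
    if (jb == pb.end() || jb->second < 0) continue;
    if (a.compare((size_t)i, w, b, (size_t)jb->second, w) != 0) continue;
    xa.push_back((int)i);
    xb.push_back(jb->second);
  }
  return DataFrame::create(_["a"] = xa, _["b"] = xb);
}

// All (x, y) with a[x, x+w) == b[y, y+w) (strand "+") or equal to the
// reverse complement of b[y, y+w) (strand "-"). 0-based.
// [[Rcpp::export]]
DataFrame cpp_dotplot(std::string a, std::string b, int w) {
  std::string brc(b.rbegin(), b.rend());
  for (auto& c : brc) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  std::vector<uint64_t> ha = kmer_hashes(a, w), hb = kmer_hashes(b, w),
                        hr = kmer_hashes(brc, w);
  std::unordered_map<uint64_t, std::vector<int>> posb, posr;
  for (size_t i = 0; i < hb.size(); ++i) posb[hb[i]].push_back((int)i);
  for (size_t i = 0; i < hr.size(); ++i) posr[hr[i]].push_back((int)i);
  int lb = (int)b.size();
  std::vector<int> x, y;
  std::vector<bool> fwd;
  for (size_t i = 0; i < ha.size(); ++i) {
    auto it = posb.find(ha[i]);
    if (it != posb.end())
      for (int j : it->second) {
        if (a.compare((size_t)i, w, b, (size_t)j, w) != 0) continue;
        x.push_back((int)i); y.push_back(j); fwd.push_back(true);
      }
    auto ir = posr.find(ha[i]);
    if (ir != posr.end())
      for (int j : ir->second) {
        if (a.compare((size_t)i, w, brc, (size_t)j, w) != 0) continue;
        x.push_back((int)i); y.push_back(lb - w - j); fwd.push_back(false);
      }
  }
  return DataFrame::create(_["x"] = x, _["y"] = y, _["forward"] = fwd);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) {
      switch (c) {
        case 'A': c = 'T'; break;
        case 'C': c = 'G'; break;
        case 'G': c = 'C'; break;
        case 'T': c = 'A'; break;
        case 'a': c = 't'; break;
        case 'c': c = 'g'; break;
        case 'g': c = 'c'; break;
        case 't': c = 'a'; break;
        default: break;
      }
    }
    out[i] = r;
  }
  return out;
}

// Edit distance if it is <= maxd, otherwise any value > maxd.
// [[Rcpp::export]]
int cpp_edit_bounded(std::string a, std::string b, int maxd) {
  return myers_bounded(a, b, maxd);
}

// Myers bit-parallel edit distance (block-based, Hyyro 2003). Exact for
// d <= bound; returns bound + 1 as soon as the bound is provably exceeded.
static int code5(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return 4;
  }
}

static int myers_bounded(const std::string& a, const std::string& b,
                         int bound) {
  int m = (int)a.size(), n = (int)b.size();
  if (m == 0 || n == 0) return std::max(m, n);
  if (std::abs(m - n) > bound) return bound + 1;
  int W = (m + 63) / 64;
  std::vector<std::array<uint64_t, 5>> peq(W, {0, 0, 0, 0, 0});
  for (int i = 0; i < m; ++i)
    peq[i >> 6][code5(a[i])] |= 1ULL << (i & 63);
  std::vector<uint64_t> Pv(W, ~0ULL), Mv(W, 0ULL);
  int score = m;
  int last = W - 1;
  int lastBit = (m - 1) & 63;
  for (int j = 0; j < n; ++j) {
    int c = code5(b[j]);
    int hin = 1;
    for (int w = 0; w < W; ++w) {
      uint64_t Eq = peq[w][c];
      uint64_t Pv_ = Pv[w], Mv_ = Mv[w];
      uint64_t Xv = Eq | Mv_;
      if (hin < 0) Eq |= 1ULL;
      uint64_t Xh = (((Eq & Pv_) + Pv_) ^ Pv_) | Eq;
      uint64_t Ph = Mv_ | ~(Xh | Pv_);
      uint64_t Mh = Pv_ & Xh;
      int hout;
      if (w == last) {
        hout = (int)((Ph >> lastBit) & 1) - (int)((Mh >> lastBit) & 1);
        score += hout;
      } else {
        hout = (int)((Ph >> 63) & 1) - (int)((Mh >> 63) & 1);
      }
      Ph = (Ph << 1) | (uint64_t)(hin > 0 ? 1 : 0);
      Mh = (Mh << 1) | (uint64_t)(hin < 0 ? 1 : 0);
      Pv[w] = Mh | ~(Xv | Ph);
      Mv[w] = Ph & Xv;
      hin = hout;
    }
    if (score - (n - j - 1) > bound) return bound + 1;
  }
  return score > bound ? bound + 1 : score;
}
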