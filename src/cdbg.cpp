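// Condensed de Bruijn graph construction over a string-set.
//
// The graph is bidirected: every k-mer and its reverse complement are one
// object, so a chromosome can traverse an edge in either orientation and
// reverse tandem duplications show up as multiplicity-2 edges. Internally we
// work on the doubled directed graph (all k-mers of the sequences AND of
// their reverse complements), condense it into unitigs, and pair each unitig
// with its reverse-complement twin at the end. Unitig breakpoints are forced
// at chromosome termini (both strands) so that every chromosome walk is a
// sequence of whole edges.
//
// K-mers are identified by a 64-bit polynomial rolling hash of their
// characters; the canonical orientation of an edge is the first-encountered
// one in a deterministic scan order, so all outputs are reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static const uint64_t HB = 1099511628211ULL; // FNV prime, odd: invertible mod 2^64

static char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

namespace {

struct Builder {
  int k;
  int n_fwd;                         // number of input segments
  std::vector<std::string> seqs;     // fwd then rc, size 2*n_fwd
  std::vector<std::vector<uint64_t>> pref; // prefix hashes per seq
  std::vector<uint64_t> pw;          // powers of HB

  uint64_t sub_hash(int j, int i, int len) const {
    return pref[j][i + len] - pref[j][i] * pw[len];
  }
  int partner(int j) const { return j < n_fwd ? j + n_fwd : j - n_fwd; }

  // distinct directed k-mers
  std::unordered_map<uint64_t, int> kid;
  std::vector<int> rep_seq, rep_pos; // representative occurrence per dk
  std::vector<int> dk_twin, dk_from, dk_to;

  // distinct directed (k-1)-mer vertices
  std::unordered_map<uint64_t, int> vid;
  std::vector<int> vrep_seq, vrep_pos, dv_twin;

  int get_vertex(int j, int i) {
    uint64_t h = sub_hash(j, i, k - 1);
    auto it = vid.find(h);
    if (it != vid.end()) return it->second;
    int id = (int)vrep_seq.size();
    vid.emplace(h, id);
    vrep_seq.push_back(j);
    vrep_pos.push_back(i);
    dv_twin.push_back(-1);
    return id;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_build_cdbg(CharacterVector segments, int k, bool both_strands = true) {
  Builder B;
  B.k = k;
  B.n_fwd = segments.size();
  int n2 = both_strands ? 2 * B.n_fwd : B.n_fwd;
  B.seqs.resize(n2);
  size_t lmax = 0;
  for (int j = 0; j < B.n_fwd; ++j) {
    B.seqs[j] = as<std::string>(segments[j]);
    if ((int)B.seqs[j].size() < k)
      stop("all segments must have length >= k");
    if (both_strands) {
      std::string rc(B.seqs[j].rbegin(), B.seqs[j].rend());
      for (auto& c : rc) c = comp_base(c);
      B.seqs[j + B.n_fwd] = rc;
    }
    lmax = std::max(lmax, B.seqs[j].size());
  }
  B.pw.resize(lmax + 1);
  B.pw[0] = 1;
  for (size_t i = 1; i <= lmax; ++i) B.pw[i] = B.pw[i - 1] * HB;
  B.pref.resize(n2);
  for (int j = 0; j < n2; ++j) {
    const std::string& s = B.seqs[j];
    B.pref[j].resize(s.size() + 1);
    B.pref[j][0] = 0;
    for (size_t i = 0; i < s.size(); ++i)
      B.pref[j][i + 1] = B.pref[j][i] * HB + (uint64_t)(unsigned char)s[i];
  }

  // --- pass 1: distinct directed k-mers ------------------------------------
  for (int j = 0; j < n2; ++j) {
    int L = (int)B.seqs[j].size();
    for (int i = 0; i + k <= L; ++i) {
      uint64_t h = B.sub_hash(j, i, k);
      auto it = B.kid.find(h);
      if (it == B.kid.end()) {
        int id = (int)B.rep_seq.size();
        B.kid.emplace(h, id);
        B.rep_seq.push_back(j);
        B.rep_pos.push_back(i);
      }
    }
  }
  int ndk = (int)B.rep_seq.size();
  B.dk_twin.assign(ndk, -1);
  B.dk_from.assign(ndk, -1);
  B.dk_to.assign(ndk, -1);

  // twins and incident vertices
  for (int d = 0; d < ndk; ++d) {
    int j = B.rep_seq[d], i = B.rep_pos[d];
    if (both_strands) {
      int pj = B.partner(j);
      int pi = (int)B.seqs[j].size() - k - i;
      B.dk_twin[d] = B.kid.at(B.sub_hash(pj, pi, k));
    } else {
      B.dk_twin[d] = d;
    }
    B.dk_from[d] = B.get_vertex(j, i);
    B.dk_to[d] = B.get_vertex(j, i + 1);
  }
  int ndv = (int)B.vrep_seq.size();
  for (int v = 0; v < ndv; ++v) {
    if (!both_strands) { B.dv_twin[v] = v; continue; }
    int j = B.vrep_seq[v], i = B.vrep_pos[v];
    int pj = B.partner(j);
    int pi = (int)B.seqs[j].size() - (k - 1) - i;
    uint64_t h = B.sub_hash(pj, pi, k - 1);
    B.dv_twin[v] = B.vid.at(h);
  }

  // --- adjacency over distinct directed k-mers -----------------------------
  std::vector<std::vector<int>> out_of(ndv);
  std::vector<int> indeg(ndv, 0);
  for (int d = 0; d < ndk; ++d) {
    out_of[B.dk_from[d]].push_back(d);
    indeg[B.dk_to[d]]++;
  }

  // forced breakpoints at segment termini, both strands
  std::vector<char> brk(ndv, 0);
  for (int j = 0; j < n2; ++j) {
    int L = (int)B.seqs[j].size();
    brk[B.vid.at(B.sub_hash(j, 0, k - 1))] = 1;
    brk[B.vid.at(B.sub_hash(j, L - (k - 1), k - 1))] = 1;
  }
  auto junction = [&](int v) {
    return brk[v] || indeg[v] != 1 || out_of[v].size() != 1;
  };

  // --- unitigs --------------------------------------------------------------
  std::vector<int> unit_of(ndk, -1), pos_in(ndk, -1);
  std::vector<std::vector<int>> units;
  auto extend = [&](int d0) {
    std::vector<int> u;
    int cur = d0;
    while (true) {
      unit_of[cur] = (int)units.size();
      pos_in[cur] = (int)u.size();
      u.push_back(cur);
      int v = B.dk_to[cur];
      if (junction(v)) break;
      int nxt = out_of[v][0];
      if (unit_of[nxt] != -1) break; // closing a cycle
      cur = nxt;
    }
    units.push_back(std::move(u));
  };
  for (int d = 0; d < ndk; ++d)
    if (unit_of[d] == -1 && junction(B.dk_from[d])) extend(d);
  // junction-free cycles: break at the smallest unassigned id, then lay the
  // twin cycle down explicitly so the two stay aligned
  for (int d = 0; d < ndk; ++d) {
    if (unit_of[d] != -1) continue;
    extend(d);
    const std::vector<int>& u = units.back();
    int td = B.dk_twin[u.back()];
    if (unit_of[td] == -1) {
      std::vector<int> tu;
      for (int q = (int)u.size() - 1; q >= 0; --q) {
        int t = B.dk_twin[u[q]];
        unit_of[t] = (int)units.size();
        pos_in[t] = (int)tu.size();
        tu.push_back(t);
      }
      units.push_back(std::move(tu));
    }
  }
  int nu = (int)units.size();

  // twin unitigs
  std::vector<int> unit_twin(nu, -1);
  for (int u = 0; u < nu; ++u) {
    int t = unit_of[B.dk_twin[units[u].back()]];
    unit_twin[u] = t;
  }

  // --- canonical edges ------------------------------------------------------
  std::vector<int> ecan(nu, 0); // signed 1-based canonical edge id
  std::vector<int> can_unit;    // canonical representative unitig per edge
  for (int u = 0; u < nu; ++u) {
    if (ecan[u] != 0) continue;
    int id = (int)can_unit.size() + 1;
    can_unit.push_back(u);
    ecan[u] = id;
    int t = unit_twin[u];
    if (t != u) ecan[t] = -id;
  }
  int ne = (int)can_unit.size();

  // canonical vertices (1-based signed); only edge endpoints are assigned
  // ids and exported — interior (k-1)-mers of condensed edges would bloat
  // the output at large k
  std::vector<int> vcan(ndv, 0);
  std::vector<int> can_vert;
  std::vector<bool> vpal;
  auto get_vcan = [&](int v) {
    if (vcan[v] != 0) return vcan[v];
    int id = (int)can_vert.size() + 1;
    can_vert.push_back(v);
    int t = B.dv_twin[v];
    vpal.push_back(t == v);
    vcan[v] = id;
    if (t != v) vcan[t] = -id;
    return id;
  };
  for (int e = 0; e < ne; ++e) {
    const std::vector<int>& u = units[can_unit[e]];
    get_vcan(B.dk_from[u[0]]);
    get_vcan(B.dk_to[u.back()]);
  }
  int nv = (int)can_vert.size();

  // spell edge labels
  CharacterVector labels(ne);
  IntegerVector elen(ne), efrom(ne), eto(ne);
  LogicalVector eself(ne);
  for (int e = 0; e < ne; ++e) {
    const std::vector<int>& u = units[can_unit[e]];
    int d0 = u[0];
    std::string lab = B.seqs[B.rep_seq[d0]].substr(B.rep_pos[d0], k);
    lab.reserve(k - 1 + u.size());
    for (size_t q = 1; q < u.size(); ++q) {
      int d = u[q];
      lab.push_back(B.seqs[B.rep_seq[d]][B.rep_pos[d] + k - 1]);
    }
    labels[e] = lab;
    elen[e] = (int)lab.size();
    efrom[e] = vcan[B.dk_from[d0]];
    eto[e] = vcan[B.dk_to[u.back()]];
    eself[e] = both_strands && (unit_twin[can_unit[e]] == can_unit[e]);
  }

  CharacterVector vlabels(nv);
  LogicalVector vpalv(nv);
  for (int v = 0; v < nv; ++v) {
    int dv = can_vert[v];
    vlabels[v] = B.seqs[B.vrep_seq[dv]].substr(B.vrep_pos[dv], k - 1);
    vpalv[v] = vpal[v];
  }

  // --- walks ----------------------------------------------------------------
  List walks(B.n_fwd);
  for (int j = 0; j < B.n_fwd; ++j) {
    int L = (int)B.seqs[j].size();
    std::vector<int> steps;
    int i = 0;
    while (i + k <= L) {
      int d = B.kid.at(B.sub_hash(j, i, k));
      if (pos_in[d] != 0)
        stop("internal error: walk does not start at a unitig boundary");
      int u = unit_of[d];
      steps.push_back(ecan[u]);
      i += (int)units[u].size();
    }
    walks[j] = IntegerVector(steps.begin(), steps.end());
  }

  return List::create(
      _["edges"] = DataFrame::create(
          _["edge_id"] = seq_len(ne), _["label"] = labels, _["length"] = elen,
          _["from"] = efrom, _["to"] = eto, _["self_rc"] = eself,
          _["stringsAsFactors"] = false),
      _["vertices"] = DataFrame::create(
          _["vertex_id"] = seq_len(nv), _["label"] = vlabels,
          _["palindromic"] = vpalv, _["stringsAsFactors"] = false),
      _["walks"] = walks, _["k"] = k);
}
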