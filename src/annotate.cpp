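#include <Rcpp.h>
#include <set>
#include <string>
#include <vector>

using namespace Rcpp;

// Longest common prefix of read and a germline sequence (V genes: the read
// starts at the 5' end of the stored V region, trimming removes 3' bases).
static inline int lcp_len(const std::string &read, const std::string &seq) {
  int m = std::min(read.size(), seq.size());
  int i = 0;
  while (i < m && read[i] == seq[i]) ++i;
  return i;
}

// Longest common suffix (J genes: read ends at the 3' end of the stored J
// region, trimming removes 5' bases).
static inline int lcs_len(const std::string &read, const std::string &seq) {
  int m = std::min(read.size(), seq.size());
  int i = 0;
  while (i < m && read[read.size() - 1 - i] == seq[seq.size() - 1 - i]) ++i;
  return i;
}

struct Scenario {
  bool valid = false;
  int n_ins = 0;   // total N-insertions (primary parsimony objective)
  int trims = 0;   // total trimmed nucleotides (first tie-break)
  int d_used = 0;  // D nucleotides used (second tie-break, maximised)
  int vi = -1, ji = -1, di = -1;
  int v_used = 0, j_used = 0;
  int d5 = 0, d3 = 0, n_vd = 0, n_dj = 0;
  int jxn_start = 0, jxn_len = 0;
  bool d_present = false;
};

// lexicographic score comparison on (n_ins, trims, -d_used); returns
// -1 if a better, +1 if b better, 0 tie.
static inline int cmp_score(const Scenario &a, const Scenario &b) {
  if (a.n_ins != b.n_ins) return a.n_ins < b.n_ins ? -1 : 1;
  if (a.trims != b.trims) return a.trims < b.trims ? -1 : 1;
  if (a.d_used != b.d_used) return a.d_used > b.d_used ? -1 : 1;
  return 0;
}

static inline bool has_stop(const std::string &read, int from) {
  for (int c = from; c + 3 <= (int)read.size(); c += 3) {
    char a = read[c], b = read[c + 1], d = read[c + 2];
    if (a == 'T' &&
        ((b == 'A' && (d == 'A' || d == 'G')) || (b == 'G' && d == 'A')))
      return true;
  }
  return false;
}

// maximal exact substring match between read and a D allele
struct DMatch { int di, i, k, m; };

//' @title Annotate TCR reads with parsimonious V(D)J recombination scenarios
//' @description Internal C++ engine. For each read, finds V/J candidates by
//'   maximal anchored exact match, enumerates junction decompositions and
//'   returns the scenario with the fewest N-insertions (ties broken by fewest
//'   trimmed nucleotides, most D nucleotides used, then allele name).
//' @noRd
// [[Rcpp::export(name = ".annotate_reads_cpp")]]
List annotate_reads_cpp(CharacterVector reads,
                        CharacterVector v_names, CharacterVector v_seqs,
                        IntegerVector v_anchor,
                        CharacterVector j_names, CharacterVector j_seqs,
                        IntegerVector j_anchor,
                        CharacterVector d_names, CharacterVector d_seqs,
                        int min_read_len, int min_vj_match, int min_d_len,
                        int max_back) {
  const int n = reads.size();
  const int nv = v_names.size(), nj = j_names.size(), nd = d_names.size();
  std::vector<std::string> vs(nv), js(nj), ds(nd);
  for (int i = 0; i < nv; ++i) vs[i] = as<std::string>(v_seqs[i]);
  for (int i = 0; i < nj; ++i) js[i] = as<std::string>(j_seqs[i]);
  for (int i = 0; i < nd; ++i) ds[i] = as<std::string>(d_seqs[i]);
  std::vector<std::string> vn(nv), jn(nj), dn(nd);
  for (int i = 0; i < nv; ++i) vn[i] = as<std::string>(v_names[i]);
  for (int i = 0; i < nj; ++i) jn[i] = as<std::string>(j_names[i]);
  for (int i = 0; i < nd; ++i) dn[i] = as<std::string>(d_names[i]);
  int dmax = 0;
  for (int i = 0; i < nd; ++i) dmax = std::max(dmax, (int)ds[i].size());

  LogicalVector unassignable(n), productive(n), in_frame(n);
  CharacterVector v_call(n), j_call(n), d_call(n);
  CharacterVector v_allele(n), d_allele(n), j_allele(n);
  IntegerVector v_trim(n), d5_trim(n), d3_trim(n), j_trim(n);
  IntegerVector n_vd(n), n_dj(n), n_vj(n);
  CharacterVector np1(n), np2(n);

  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    const int L = read.size();
    unassignable[r] = true;
    v_call[r] = NA_STRING; j_call[r] = NA_STRING; d_call[r] = NA_STRING;
    v_allele[r] = NA_STRING; d_allele[r] = NA_STRING; j_allele[r] = NA_STRING;
    v_trim[r] = NA_INTEGER; d5_trim[r] = NA_INTEGER; d3_trim[r] = NA_INTEGER;
    j_trim[r] = NA_INTEGER; n_vd[r] = NA_INTEGER; n_dj[r] = NA_INTEGER;
    n_vj[r] = NA_INTEGER; np1[r] = NA_STRING; np2[r] = NA_STRING;
    productive[r] = NA_LOGICAL; in_frame[r] = NA_LOGICAL;
    if (L < min_read_len) continue;

    // V candidates: alleles maximising the anchored 5' exact match.
    int vmax = 0;
    std::vector<int> vcand;
    for (int i = 0; i < nv; ++i) {
      int m = lcp_len(read, vs[i]);
      if (m > vmax) { vmax = m; vcand.clear(); vcand.push_back(i); }
      else if (m == vmax && m > 0) vcand.push_back(i);
    }
    // J candidates: alleles maximising the anchored 3' exact match.
    int jmax = 0;
    std::vector<int> jcand;
    for (int i = 0; i < nj; ++i) {
      int m = lcs_len(read, js[i]);
      if (m > jmax) { jmax = m; jcand.clear(); jcand.push_back(i); }
      else if (m == jmax && m > 0) jcand.push_back(i);
    }
    if (vmax < min_vj_match || jmax < min_vj_match) continue;

    // all maximal read/D-allele matches of length >= min_d_len, found once;
    // a maximal match inside any junction window is one of these, clipped
    std::vector<DMatch> dmatch;
    for (int di = 0; di < nd; ++di) {
      const std::string &dsq = ds[di];
      const int lend = dsq.size();
      for (int i = 0; i < L; ++i) {
        for (int k = 0; k < lend; ++k) {
          if (read[i] != dsq[k]) continue;
          if (i > 0 && k > 0 && read[i - 1] == dsq[k - 1]) continue;
          int m = 1;
          while (i + m < L && k + m < lend && read[i + m] == dsq[k + m]) ++m;
          if (m >= min_d_len) dmatch.push_back({di, i, k, m});
        }
      }
    }

    Scenario best;
    std::set<std::string> d_ties;  // D alleles achieving the optimal score
    for (size_t vq = 0; vq < vcand.size(); ++vq) {
      const int vi = vcand[vq];
      const int lenv = vs[vi].size();
      for (size_t jq = 0; jq < jcand.size(); ++jq) {
        const int ji = jcand[jq];
        const int lenj = js[ji].size();
        const int vlo = std::max(0, vmax - max_back);
        const int jlo = std::max(0, jmax - max_back);
        for (int vu = vmax; vu >= vlo; --vu) {
          for (int ju = jmax; ju >= jlo; --ju) {
            if (vu + ju > L) continue;
            const int jl = L - vu - ju;
            // even a maximal D match cannot reach the current optimum
            if (best.valid && jl - dmax > best.n_ins) continue;
            const int base_trims = (lenv - vu) + (lenj - ju);

            // D-absent decomposition: whole junction is V-J insertion.
            Scenario c;
            c.valid = true; c.n_ins = jl; c.trims = base_trims; c.d_used = 0;
            c.vi = vi; c.ji = ji; c.di = -1; c.v_used = vu; c.j_used = ju;
            c.jxn_start = vu; c.jxn_len = jl; c.d_present = false;
            int s = best.valid ? cmp_score(c, best) : -1;
            if (s < 0) {
              best = c; d_ties.clear();
            } else if (s == 0) {
              if (vn[c.vi] < vn[best.vi] ||
                  (vn[c.vi] == vn[best.vi] && jn[c.ji] < jn[best.ji]))
                best = c;
            }

            if (jl < min_d_len) continue;
            // clip precomputed read-level D matches to the junction window
            const int wlo = vu, whi = vu + jl;  // [wlo, whi)
            for (size_t q = 0; q < dmatch.size(); ++q) {
              const DMatch &dm = dmatch[q];
              int i0 = std::max(dm.i, wlo);
              int e0 = std::min(dm.i + dm.m, whi);
              int m2 = e0 - i0;
              if (m2 < min_d_len) continue;
              int k2 = dm.k + (i0 - dm.i);
              const int lend = ds[dm.di].size();
              Scenario cd;
              cd.valid = true; cd.n_ins = jl - m2;
              cd.trims = base_trims + k2 + (lend - k2 - m2);
              cd.d_used = m2; cd.vi = vi; cd.ji = ji; cd.di = dm.di;
              cd.v_used = vu; cd.j_used = ju;
              cd.d5 = k2; cd.d3 = lend - k2 - m2;
              cd.n_vd = i0 - wlo; cd.n_dj = whi - e0;
              cd.jxn_start = vu; cd.jxn_len = jl; cd.d_present = true;
              int sc = best.valid ? cmp_score(cd, best) : -1;
              if (sc < 0) {
                best = cd; d_ties.clear(); d_ties.insert(dn[dm.di]);
              } else if (sc == 0) {
                d_ties.insert(dn[dm.di]);
                if (vn[cd.vi] < vn[best.vi] ||
                    (vn[cd.vi] == vn[best.vi] &&
                     (dn[cd.di] < dn[best.di] ||
                      (dn[cd.di] == dn[best.di] &&
                       jn[cd.ji] < jn[best.ji]))))
                  best = cd;
              }
            }
          }
        }
      }
    }
    if (!best.valid) continue;

    unassignable[r] = false;
    std::set<std::string> vset, jset;
    for (size_t q = 0; q < vcand.size(); ++q) vset.insert(vn[vcand[q]]);
    for (size_t q = 0; q < jcand.size(); ++q) jset.insert(jn[jcand[q]]);
    std::string vj, jj, dj;
    for (std::set<std::string>::iterator it = vset.begin(); it != vset.end(); ++it)
      vj += (vj.empty() ? "" : ",") + *it;
    for (std::set<std::string>::iterator it = jset.begin(); it != jset.end(); ++it)
      jj += (jj.empty() ? "" : ",") + *it;
    for (std::set<std::string>::iterator it = d_ties.begin(); it != d_ties.end(); ++it)
      dj += (dj.empty() ? "" : ",") + *it;

    v_call[r] = vj; j_call[r] = jj;
    v_allele[r] = vn[best.vi]; j_allele[r] = jn[best.ji];
    v_trim[r] = (int)vs[best.vi].size() - best.v_used;
    j_trim[r] = (int)js[best.ji].size() - best.j_used;
    const std::string jxn = read.substr(best.jxn_start, best.jxn_len);
    if (best.d_present) {
      d_call[r] = dj;
      d_allele[r] = dn[best.di];
      d5_trim[r] = best.d5; d3_trim[r] = best.d3;
      n_vd[r] = best.n_vd; n_dj[r] = best.n_dj;
      np1[r] = jxn.substr(0, best.n_vd);
      np2[r] = jxn.substr(best.jxn_len - best.n_dj, best.n_dj);
    } else {
      d_call[r] = "";
      n_vj[r] = best.jxn_len;
      np1[r] = jxn;
      np2[r] = "";
    }

    // productivity from frame anchors of the chosen V and J alleles
    const int av = v_anchor[best.vi];
    const int jpos = L - (int)js[best.ji].size() + j_anchor[best.ji];
    bool inf = ((jpos - av) % 3) == 0;
    in_frame[r] = inf;
    productive[r] = inf && !has_stop(read, av);
  }

  return List::create(
      _["unassignable"] = unassignable, _["v_call"] = v_call,
      _["d_call"] = d_call, _["j_call"] = j_call, _["v_allele"] = v_allele,
      _["d_allele"] = d_allele, _["j_allele"] = j_allele,
      _["v_trim"] = v_trim, _["d5_trim"] = d5_trim, _["d3_trim"] = d3_trim,
      _["j_trim"] = j_trim, _["n_vd"] = n_vd, _["n_dj"] = n_dj,
      _["n_vj"] = n_vj, _["np1"] = np1, _["np2"] = np2,
      _["in_frame"] = in_frame, _["productive"] = productive);
}

//' @title Frame/stop productivity classification
//' @description Internal helper: a read is productive iff the J frame anchor
//'   (at read position jpos) is congruent mod 3 with the V frame anchor (read
//'   position av) and no stop codon occurs in that frame from av onwards.
//' @noRd
// [[Rcpp::export(name = ".productive_cpp")]]
List productive_cpp(CharacterVector reads, IntegerVector av, IntegerVector jpos) {
  const int n = reads.size();
  LogicalVector in_frame(n), productive(n);
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    bool inf = ((jpos[r] - av[r]) % 3) == 0;
    in_frame[r] = inf;
    productive[r] = inf && !has_stop(read, av[r]);
  }
  return List::create(_["in_frame"] = in_frame, _["productive"] = productive);
}
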