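#include <Rcpp.h>
#include <cstring>
#include <string>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Hamming distance between two equal-length strings.  Any byte difference
// counts as a mismatch, so 'N' mismatches every base including 'N' vs 'A'.
// [[Rcpp::export]]
int C_hamming(std::string a, std::string b) {
  if (a.size() != b.size())
    stop("hamming distance requires equal-length strings");
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] != b[i]) ++mm;
  return mm;
}

// Hamming distance of one candidate against many equal-length references.
// References whose length differs from the candidate get NA.
// [[Rcpp::export]]
IntegerVector C_hamming_vec(std::string x, CharacterVector ys) {
  int n = ys.size();
  IntegerVector out(n);
  int lx = (int)x.size();
  for (int i = 0; i < n; ++i) {
    const char* y = CHAR(STRING_ELT(ys, i));
    int ly = (int)strlen(y);
    if (ly != lx) { out[i] = NA_INTEGER; continue; }
    int mm = 0;
    for (int j = 0; j < lx; ++j)
      if (x[j] != y[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector C_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (seqs[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char* s = CHAR(STRING_ELT(seqs, i));
    int len = (int)strlen(s);
    std::string r(len, 'N');
    for (int j = 0; j < len; ++j) {
      char c = s[len - 1 - j];
      switch (c) {
        case 'A': r[j] = 'T'; break;
        case 'C': r[j] = 'G'; break;
        case 'G': r[j] = 'C'; break;
        case 'T': r[j] = 'A'; break;
        case 'a': r[j] = 't'; break;
        case 'c': r[j] = 'g'; break;
        case 'g': r[j] = 'c'; break;
        case 't': r[j] = 'a'; break;
        default:  r[j] = c;  break;
      }
    }
    out[i] = r;
  }
  return out;
}

// Exact substring scan of every read against a set of guide sequences.
// Returns, per read: total occurrence count, number of distinct guide
// sequences hit, 0-based position of the leftmost hit and its guide index
// (1-based, first-in-set for duplicated sequences); -1 when no hit.
// [[Rcpp::export]]
List C_scan_guides(CharacterVector reads, CharacterVector guides) {
  std::unordered_map<int, std::unordered_map<std::string, int> > by_len;
  for (int i = 0; i < guides.size(); ++i) {
    std::string g = as<std::string>(guides[i]);
    std::unordered_map<std::string, int>& m = by_len[(int)g.size()];
    if (!m.count(g)) m[g] = i + 1;
  }
  int n = reads.size();
  IntegerVector n_occ(n), n_distinct(n), pos(n), guide(n);
  for (int r = 0; r < n; ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)strlen(s);
    int occ = 0, fp = -1, fg = -1;
    std::unordered_set<int> distinct;
    for (std::unordered_map<int, std::unordered_map<std::string, int> >::iterator
           kv = by_len.begin(); kv != by_len.end(); ++kv) {
      int L = kv->first;
      for (int p = 0; p + L <= len; ++p) {
        std::unordered_map<std::string, int>::iterator it =
          kv->second.find(std::string(s + p, L));
        if (it != kv->second.end()) {
          ++occ;
          distinct.insert(it->second);
          if (fp < 0 || p < fp) { fp = p; fg = it->second; }
        }
      }
    }
    n_occ[r] = occ;
    n_distinct[r] = (int)distinct.size();
    pos[r] = fp;
    guide[r] = fg;
  }
  return List::create(_["n_occ"] = n_occ, _["n_distinct"] = n_distinct,
                      _["pos"] = pos, _["guide"] = guide);
}

// Anchored trimming of a batch of reads.  Searches anchor5 at offsets
// [omin, omax]; among offsets with Hamming mismatches <= max_mm picks the
// minimal-mismatch one, ties to the smallest offset.  The candidate runs from
// the end of anchor5 to the leftmost anchor3 match at least gmin bases
// downstream, or to gmax bases (clipped at the read end) when anchor3 is
// empty or not found.
// [[Rcpp::export]]
List C_trim_reads(CharacterVector reads, std::string anchor5,
                  std::string anchor3, int omin, int omax, int max_mm,
                  int gmin, int gmax) {
  int n = reads.size();
  int l5 = (int)anchor5.size(), l3 = (int)anchor3.size();
  if (omin < 0) omin = 0;
  LogicalVector trimmed(n);
  CharacterVector cand(n);
  IntegerVector stag(n, NA_INTEGER), mm5(n, NA_INTEGER);
  for (int r = 0; r < n; ++r) {
    trimmed[r] = false;
    cand[r] = NA_STRING;
    if (reads[r] == NA_STRING) continue;
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)strlen(s);
    int best_o = -1, best_mm = max_mm + 1;
    for (int o = omin; o <= omax; ++o) {
      if (o + l5 > len) break;
      int m = 0;
      for (int i = 0; i < l5 && m <= max_mm; ++i)
        if (s[o + i] != anchor5[i]) ++m;
      if (m <= max_mm && m < best_mm) { best_mm = m; best_o = o; }
    }
    if (best_o < 0) continue;
    int start = best_o + l5;
    int end = -1;
    if (l3 > 0) {
      for (int p = start + gmin; p + l3 <= len; ++p) {
        int m = 0;
        for (int i = 0; i < l3 && m <= max_mm; ++i)
          if (s[p + i] != anchor3[i]) ++m;
        if (m <= max_mm) { end = p; break; }
      }
    }
    if (end < 0) {
      end = start + gmax;
      if (end > len) end = len;
    }
    int clen = end - start;
    if (clen < gmin) continue;
    trimmed[r] = true;
    cand[r] = std::string(s + start, clen);
    stag[r] = best_o;
    mm5[r] = best_mm;
  }
  return List::create(_["trimmed"] = trimmed, _["candidate"] = cand,
                      _["stagger"] = stag, _["anchor5_mm"] = mm5);
}
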