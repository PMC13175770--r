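#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Semi-global ("glocal") alignment: the guide spacer is consumed end-to-end,
// the genomic window has free end gaps. The DP minimises edit distance
// (Levenshtein); the Needleman-Wunsch score (match +1, mismatch -1, gap -2)
// is computed from the traceback of that optimal-distance alignment.

// [[Rcpp::export(name = ".glocal_align_cpp")]]
List glocal_align_cpp(std::string spacer, std::string window,
                      bool anchor_end = false) {
  const int n = (int) spacer.size();
  const int m = (int) window.size();
  // D[i][j]: min edits aligning spacer[0..i) to a suffix of window[0..j)
  std::vector<std::vector<int> > D(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 0; i <= n; ++i) D[i][0] = i;
  for (int j = 0; j <= m; ++j) D[0][j] = 0;   // free leading window gap
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = D[i - 1][j - 1] + (spacer[i - 1] == window[j - 1] ? 0 : 1);
      int del = D[i - 1][j] + 1;   // spacer base vs gap
      int ins = D[i][j - 1] + 1;   // window base vs gap
      D[i][j] = std::min(sub, std::min(del, ins));
    }
  }
  // free trailing window gap: best end column, leftmost on ties
  // (anchor_end: traceback from the final column instead)
  int best_j = 0, best = D[n][0];
  if (anchor_end) { best_j = m; best = D[n][m]; }
  else for (int j = 1; j <= m; ++j)
    if (D[n][j] < best) { best = D[n][j]; best_j = j; }

  // traceback; preference diag > up > left for determinism
  std::string a_sp, a_win;
  int i = n, j = best_j, mm = 0, ins_n = 0, del_n = 0, match_n = 0;
  while (i > 0) {
    if (j > 0 && D[i][j] == D[i - 1][j - 1] +
        (spacer[i - 1] == window[j - 1] ? 0 : 1)) {
      if (spacer[i - 1] == window[j - 1]) ++match_n; else ++mm;
      a_sp.push_back(spacer[i - 1]); a_win.push_back(window[j - 1]);
      --i; --j;
    } else if (D[i][j] == D[i - 1][j] + 1) {
      ++del_n;
      a_sp.push_back(spacer[i - 1]); a_win.push_back('-');
      --i;
    } else {
      ++ins_n;
      a_sp.push_back('-'); a_win.push_back(window[j - 1]);
      --j;
    }
  }
  std::reverse(a_sp.begin(), a_sp.end());
  std::reverse(a_win.begin(), a_win.end());
  int start = j;                      // 0-based start of aligned window span
  int score = match_n - mm - 2 * (ins_n + del_n);
  return List::create(
    _["distance"] = best, _["start"] = start, _["end"] = best_j,
    _["mismatches"] = mm, _["insertions"] = ins_n, _["deletions"] = del_n,
    _["aligned_spacer"] = a_sp, _["aligned_window"] = a_win,
    _["score"] = score);
}

// Per-end-position semi-global distances of `spacer` against `text`:
// out[j] = min edit distance of the spacer to any substring of text ending
// at 0-based position j (inclusive). Rolling two-row DP.

// [[Rcpp::export(name = ".scan_text_cpp")]]
IntegerVector scan_text_cpp(std::string spacer, std::string text) {
  const int n = (int) spacer.size();
  const int m = (int) text.size();
  IntegerVector out(m);
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int i = 0; i <= n; ++i) prev[i] = i;
  for (int j = 1; j <= m; ++j) {
    cur[0] = 0;
    const char c = text[j - 1];
    for (int i = 1; i <= n; ++i) {
      int sub = prev[i - 1] + (spacer[i - 1] == c ? 0 : 1);
      int del = prev[i] + 1;
      int ins = cur[i - 1] + 1;
      cur[i] = std::min(sub, std::min(del, ins));
    }
    out[j - 1] = cur[n];
    std::swap(prev, cur);
  }
  return out;
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'C': c = 'G'; break;
      case 'G': c = 'C'; break; case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

// Deliberately naive read mapper: exact k-mer seed at read offset 0 on both
// strands, ungapped extension counting mismatches, unique-best placement.
// Ties across loci -> "ambiguous"; no hit within max_mm -> "unmapped".
// Contract: correctness on low-error synthetic reads, not sensitivity.

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(CharacterVector contigs, CharacterVector reads,
                        int seed_len, int max_mm) {
  const int nc = contigs.size();
  std::vector<std::string> refs(nc);
  for (int i = 0; i < nc; ++i) refs[i] = as<std::string>(contigs[i]);

  // index: packed 2-bit seed -> list of (contig, pos)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > idx;
  for (int c = 0; c < nc; ++c) {
    const std::string &s = refs[c];
    if ((int) s.size() < seed_len) continue;
    uint64_t key = 0; int valid = 0;
    const uint64_t mask = (seed_len == 32) ? ~0ULL
      : ((1ULL << (2 * seed_len)) - 1);
    for (int p = 0; p < (int) s.size(); ++p) {
      int b = base2bit(s[p]);
      if (b < 0) { valid = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) b) & mask;
      if (++valid >= seed_len) idx[key].push_back({c, p - seed_len + 1});
    }
  }

  const int nr = reads.size();
  IntegerVector contig_out(nr), pos_out(nr), nm_out(nr);
  CharacterVector strand_out(nr), status_out(nr);

  for (int r = 0; r < nr; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string rev = revcomp_str(fwd);
    int best_nm = max_mm + 1, best_contig = -1, best_pos = -1, n_best = 0;
    char best_strand = '+';
    for (int ori = 0; ori < 2; ++ori) {
      const std::string &rd = (ori == 0) ? fwd : rev;
      if ((int) rd.size() < seed_len) continue;
      uint64_t key = 0; bool ok = true;
      for (int p = 0; p < seed_len; ++p) {
        int b = base2bit(rd[p]);
        if (b < 0) { ok = false; break; }
        key = (key << 2) | (uint64_t) b;
      }
      if (!ok) continue;
      auto it = idx.find(key);
      if (it == idx.end()) continue;
      for (auto &hit : it->second) {
        const std::string &ref = refs[hit.first];
        if (hit.second + (int) rd.size() > (int) ref.size()) continue;
        int nm = 0;
        for (int p = seed_len; p < (int) rd.size() && nm <= max_mm; ++p)
          if (rd[p] != ref[hit.second + p]) ++nm;
        if (nm < best_nm) {
          best_nm = nm; best_contig = hit.first; best_pos = hit.second;
          best_strand = (ori == 0) ? '+' : '-'; n_best = 1;
        } else if (nm == best_nm &&
                   !(hit.first == best_contig && hit.second == best_pos &&
                     best_strand == ((ori == 0) ? '+' : '-'))) {
          ++n_best;
        }
      }
    }
    if (best_nm > max_mm) {
      contig_out[r] = NA_INTEGER; pos_out[r] = NA_INTEGER;
      nm_out[r] = NA_INTEGER; strand_out[r] = NA_STRING;
      status_out[r] = "unmapped";
    } else {
      contig_out[r] = best_contig + 1; pos_out[r] = best_pos;
      nm_out[r] = best_nm;
      strand_out[r] = std::string(1, best_strand);
      status_out[r] = (n_best == 1) ? "mapped" : "ambiguous";
    }
  }
  return DataFrame::create(
    _["contig"] = contig_out, _["pos"] = pos_out, _["strand"] = strand_out,
    _["nm"] = nm_out, _["status"] = status_out,
    _["stringsAsFactors"] = false);
}

// Banded global edit-distance alignment of full-length amplicon reads to the
// amplicon reference; returns one row per indel op (type I/D, 0-based ref
// position, length). Reads are expected to span the amplicon.

// [[Rcpp::export(name = ".align_amplicon_cpp")]]
DataFrame align_amplicon_cpp(std::string ref, CharacterVector reads, int band) {
  const int m = (int) ref.size();
  std::vector<int> out_read, out_pos, out_len;
  std::vector<char> out_type;
  std::vector<std::string> out_seq;    // deleted ref bases / inserted read bases
  const int BIG = 1 << 28;

  for (int r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    const int n = (int) rd.size();
    int b = std::max(band, std::abs(n - m) + 2);
    // D[i][j] over band |j - i| <= b, stored dense for simplicity (amplicons
    // are short); traceback matrix of moves.
    std::vector<std::vector<int> > D(n + 1, std::vector<int>(m + 1, BIG));
    D[0][0] = 0;
    for (int j = 1; j <= std::min(m, b); ++j) D[0][j] = j;
    for (int i = 1; i <= std::min(n, b); ++i) D[i][0] = i;
    for (int i = 1; i <= n; ++i) {
      int jlo = std::max(1, i - b), jhi = std::min(m, i + b);
      for (int j = jlo; j <= jhi; ++j) {
        int best = BIG;
        if (D[i - 1][j - 1] < BIG)
          best = D[i - 1][j - 1] + (rd[i - 1] == ref[j - 1] ? 0 : 1);
        if (D[i - 1][j] < BIG) best = std::min(best, D[i - 1][j] + 1);
        if (D[i][j - 1] < BIG) best = std::min(best, D[i][j - 1] + 1);
        D[i][j] = best;
      }
    }
    // traceback from (n, m); diag > up (ins in read) > left (del from ref)
    int i = n, j = m;
    // current run of I/D being collected (alignment walked right-to-left)
    while (i > 0 || j > 0) {
      if (i > 0 && j > 0 && D[i - 1][j - 1] < BIG &&
          D[i][j] == D[i - 1][j - 1] + (rd[i - 1] == ref[j - 1] ? 0 : 1)) {
        --i; --j;
      } else if (i > 0 && D[i - 1][j] < BIG && D[i][j] == D[i - 1][j] + 1) {
        // read base absent from ref: insertion at ref position j (0-based gap)
        int len = 0; std::string ins_seq;
        while (i > 0 && D[i - 1][j] < BIG && D[i][j] == D[i - 1][j] + 1) {
          ins_seq.insert(ins_seq.begin(), rd[i - 1]);
          --i; ++len;
        }
        out_read.push_back(r + 1); out_type.push_back('I');
        out_pos.push_back(j); out_len.push_back(len);
        out_seq.push_back(ins_seq);
      } else {
        // ref base absent from read: deletion covering ref [j-len, j)
        int len = 0;
        while (j > 0 && D[i][j - 1] < BIG && D[i][j] == D[i][j - 1] + 1) {
          --j; ++len;
        }
        out_read.push_back(r + 1); out_type.push_back('D');
        out_pos.push_back(j); out_len.push_back(len);
        out_seq.push_back(ref.substr(j, len));
      }
    }
  }
  CharacterVector type_out(out_type.size());
  for (size_t k = 0; k < out_type.size(); ++k)
    type_out[k] = std::string(1, out_type[k]);
  return DataFrame::create(
    _["read"] = IntegerVector(out_read.begin(), out_read.end()),
    _["type"] = type_out,
    _["ref_pos"] = IntegerVector(out_pos.begin(), out_pos.end()),
    _["length"] = IntegerVector(out_len.begin(), out_len.end()),
    _["seq"] = CharacterVector(out_seq.begin(), out_seq.end()),
    _["stringsAsFactors"] = false);
}
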