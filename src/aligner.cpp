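// Seeded banded alignment against a circular reference, pileup
// accumulation, and edit-distance screening for NUMT exclusion.
//
// Circularity is handled by indexing and aligning against the doubled
// reference sequence; reported coordinates are left in the doubled
// ("unwrapped") frame and folded back modulo the genome length in R.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const int NEG_INF = std::numeric_limits<int>::min() / 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0; case 'C': return 1;
  case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

// 2-bit encode a k-mer; returns false if it contains a non-ACGT base
static bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

struct KmerIndex {
  std::unordered_map<uint64_t, std::vector<int>> map;  // 0-based positions
  int k;
};

static KmerIndex build_index(const std::string& seq, int k) {
  KmerIndex idx; idx.k = k;
  if ((int)seq.size() < k) return idx;
  for (int i = 0; i + k <= (int)seq.size(); ++i) {
    uint64_t code;
    if (encode_kmer(seq.c_str() + i, k, code)) idx.map[code].push_back(i);
  }
  return idx;
}

struct AlnResult {
  bool aligned = false;
  int ref_start = -1;     // 0-based in doubled frame
  int score = NEG_INF;
  int nm = 0;             // mismatches + gap bases
  std::string cigar;
};

// Fitting alignment: the read is global, the reference window is free at
// both ends. Affine gaps, optional band around an expected diagonal.
// diag0 = expected (j - i) offset of the read in the window; band < 0
// disables banding (full DP).
static AlnResult fit_align(const std::string& read, const std::string& win,
                           int match, int mismatch, int gap_open,
                           int gap_extend, int band, int diag0) {
  const int m = read.size(), w = win.size();
  AlnResult res;
  if (m == 0 || w == 0) return res;

  auto in_band = [&](int i, int j) {
    if (band < 0) return true;
    int d = j - i;
    return d >= diag0 - band && d <= diag0 + band;
  };

  // H: best ending in match/mismatch; E: gap in read (deletion, consumes
  // ref); F: gap in ref (insertion, consumes read)
  std::vector<std::vector<int>> H(m + 1, std::vector<int>(w + 1, NEG_INF));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(w + 1, NEG_INF));
  std::vector<std::vector<int>> F(m + 1, std::vector<int>(w + 1, NEG_INF));
  std::vector<std::vector<int>> best(m + 1, std::vector<int>(w + 1, NEG_INF));

  for (int j = 0; j <= w; ++j) best[0][j] = 0;  // free ref prefix
  for (int i = 1; i <= m; ++i) {
    // leading read bases unmatched to ref: insertion run
    F[i][0] = gap_open + (i - 1) * gap_extend;
    best[i][0] = F[i][0];
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= w; ++j) {
      if (!in_band(i, j)) continue;
      int diag = best[i - 1][j - 1];
      if (diag > NEG_INF) {
        int s = (read[i - 1] == win[j - 1]) ? match : mismatch;
        H[i][j] = diag + s;
      }
      // E: consume ref base j (deletion in read)
      int e_open = (best[i][j - 1] > NEG_INF) ? best[i][j - 1] + gap_open
                                              : NEG_INF;
      int e_ext = (E[i][j - 1] > NEG_INF) ? E[i][j - 1] + gap_extend
                                          : NEG_INF;
      E[i][j] = std::max(e_open, e_ext);
      // F: consume read base i (insertion relative to ref)
      int f_open = (best[i - 1][j] > NEG_INF) ? best[i - 1][j] + gap_open
                                              : NEG_INF;
      int f_ext = (F[i - 1][j] > NEG_INF) ? F[i - 1][j] + gap_extend
                                          : NEG_INF;
      F[i][j] = std::max(f_open, f_ext);
      best[i][j] = std::max({H[i][j], E[i][j], F[i][j]});
    }
  }

  int best_j = -1, best_score = NEG_INF;
  for (int j = 0; j <= w; ++j) {
    if (best[m][j] > best_score) { best_score = best[m][j]; best_j = j; }
  }
  if (best_j < 0 || best_score <= NEG_INF / 2) return res;

  // traceback
  std::string ops; ops.reserve(m + 8);
  int i = m, j = best_j, nm = 0;
  char state = 'B';  // decide from best
  while (i > 0) {
    int cur = (state == 'B') ? best[i][j] :
              (state == 'H') ? H[i][j] :
              (state == 'E') ? E[i][j] : F[i][j];
    if (state == 'B') {
      if (j > 0 && cur == H[i][j]) state = 'H';
      else if (j > 0 && cur == E[i][j]) state = 'E';
      else state = 'F';
      continue;
    }
    if (state == 'H') {
      ops.push_back('M');
      if (read[i - 1] != win[j - 1]) ++nm;
      --i; --j; state = 'B';
    } else if (state == 'E') {
      ops.push_back('D'); ++nm;
      int prev_open = (best[i][j - 1] > NEG_INF) ? best[i][j - 1] + gap_open
                                                 : NEG_INF;
      if (cur == prev_open) state = 'B';
      --j;
      if (j == 0) state = 'B';
    } else {  // F
      ops.push_back('I'); ++nm;
      if (i >= 1 && j >= 0) {
        int prev_open = (best[i - 1][j] > NEG_INF)
                          ? best[i - 1][j] + gap_open : NEG_INF;
        if (cur == prev_open) state = 'B';
      }
      --i;
    }
  }
  // i == 0: remaining j is the free reference prefix; alignment starts at j
  std::reverse(ops.begin(), ops.end());
  // trailing deletions against the free ref suffix cannot occur (we end at
  // best_j); leading read insertions become soft clips
  int lead_I = 0, tail_I = 0;
  int n = ops.size();
  while (lead_I < n && ops[lead_I] == 'I') ++lead_I;
  while (tail_I < n - lead_I && ops[n - 1 - tail_I] == 'I') ++tail_I;
  // run-length encode with end I -> S
  std::string cigar;
  int pos = 0;
  auto flush = [&](char op, int len) {
    if (len > 0) cigar += std::to_string(len) + op;
  };
  int run_len = 0; char run_op = 0;
  for (int t = 0; t < n; ++t) {
    char op = ops[t];
    if (op == 'I' && (t < lead_I || t >= n - tail_I)) op = 'S';
    if (op == run_op) { ++run_len; }
    else { flush(run_op, run_len); run_op = op; run_len = 1; }
  }
  flush(run_op, run_len);
  (void)pos;
  // nm counted soft-clipped leading/trailing I as gaps; correct that
  nm -= lead_I + tail_I;

  res.aligned = true;
  res.score = best_score;
  res.nm = nm;
  res.cigar = cigar;
  res.ref_start = j;  // 0-based start within window
  return res;
}

// [[Rcpp::export(name = ".fit_align_cpp")]]
List fit_align_cpp(std::string read, std::string window, int match,
                   int mismatch, int gap_open, int gap_extend, int band,
                   int diag0) {
  AlnResult r = fit_align(read, window, match, mismatch, gap_open,
                          gap_extend, band, diag0);
  return List::create(_["aligned"] = r.aligned, _["score"] = r.score,
                      _["ref_start"] = r.ref_start + 1,
                      _["cigar"] = r.cigar, _["nm"] = r.nm);
}

// [[Rcpp::export(name = ".align_reads_cpp")]]
DataFrame align_reads_cpp(CharacterVector seqs, std::string genome_doubled,
                          int genome_len, int k, int match, int mismatch,
                          int gap_open, int gap_extend, int band,
                          double min_frac) {
  KmerIndex idx = build_index(genome_doubled, k);
  int n = seqs.size();
  LogicalVector aligned(n);
  IntegerVector ref_start(n), score(n), nm(n);
  CharacterVector cigar(n);

  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(seqs[r]);
    int m = read.size();
    AlnResult bestr;
    if (m < k) { aligned[r] = false; continue; }

    // seed at a few offsets; vote on candidate start positions
    std::vector<int> offsets = {0, m / 2, m - k};
    std::unordered_map<int, int> votes;
    for (int off : offsets) {
      uint64_t code;
      if (!encode_kmer(read.c_str() + off, k, code)) continue;
      auto it = idx.map.find(code);
      if (it == idx.map.end()) continue;
      if (it->second.size() > 64) continue;  // uninformative repeat
      for (int p : it->second) {
        int cand = p - off;
        if (cand < 0 || cand >= genome_len) continue;  // fold to 1st copy
        votes[cand] += 1;
      }
    }
    // collect unique candidates with at least one vote
    std::vector<int> cands;
    for (auto& kv : votes) if (kv.second > 0) cands.push_back(kv.first);
    std::sort(cands.begin(), cands.end());
    if (cands.size() > 50) cands.resize(50);

    for (int cand : cands) {
      if (cand < 0) continue;
      // quick Hamming check at the candidate offset
      if (cand + m <= (int)genome_doubled.size()) {
        int mm = 0;
        for (int t = 0; t < m && mm <= 3; ++t) {
          if (read[t] != genome_doubled[cand + t]) ++mm;
        }
        if (mm <= 3) {
          int sc = (m - mm) * match + mm * mismatch;
          if (sc > bestr.score) {
            bestr.aligned = true; bestr.score = sc; bestr.nm = mm;
            bestr.ref_start = cand;
            bestr.cigar = std::to_string(m) + "M";
          }
          continue;
        }
      }
      // banded DP in a padded window
      int pad = band;
      int lo = std::max(0, cand - pad);
      int hi = std::min((int)genome_doubled.size(), cand + m + pad);
      if (hi - lo < m / 2) continue;
      std::string win = genome_doubled.substr(lo, hi - lo);
      AlnResult a = fit_align(read, win, match, mismatch, gap_open,
                              gap_extend, band, cand - lo);
      if (a.aligned && a.score > bestr.score) {
        a.ref_start += lo;
        bestr = a;
      }
    }
    int min_score = (int)(min_frac * m * match);
    if (bestr.aligned && bestr.score >= min_score) {
      aligned[r] = true;
      ref_start[r] = bestr.ref_start + 1;  // 1-based, doubled frame
      score[r] = bestr.score;
      nm[r] = bestr.nm;
      cigar[r] = bestr.cigar;
    } else {
      aligned[r] = false;
      ref_start[r] = NA_INTEGER; score[r] = NA_INTEGER; nm[r] = NA_INTEGER;
      cigar[r] = NA_STRING;
    }
  }
  return DataFrame::create(_["aligned"] = aligned, _["ref_start"] = ref_start,
                           _["score"] = score, _["nm"] = nm,
                           _["cigar"] = cigar,
                           _["stringsAsFactors"] = false);
}

// Accumulate a stranded pileup from filtered alignments.
// counts matrix: genome_len rows x 10 columns:
//   A+,C+,G+,T+,del+,A-,C-,G-,T-,del-
// Insertions are returned as parallel vectors (anchor position in the
// folded frame, inserted sequence, strand).
// keep_lo/keep_hi bound the usable reference span per read in the doubled
// frame (primer trimming / HVII soft clips); min_q masks low-quality
// bases.
// [[Rcpp::export(name = ".pileup_cpp")]]
List pileup_cpp(CharacterVector seqs, CharacterVector quals,
                IntegerVector ref_starts, CharacterVector cigars,
                IntegerVector strands, IntegerVector keep_lo,
                IntegerVector keep_hi, int genome_len, int min_q) {
  IntegerMatrix counts(genome_len, 10);
  std::vector<int> ins_pos; std::vector<std::string> ins_seq;
  std::vector<int> ins_strand;

  int n = seqs.size();
  for (int r = 0; r < n; ++r) {
    if (ref_starts[r] == NA_INTEGER) continue;
    std::string seq = as<std::string>(seqs[r]);
    std::string qual = as<std::string>(quals[r]);
    std::string cig = as<std::string>(cigars[r]);
    int strand = strands[r];  // 0 fwd, 1 rev
    int lo = keep_lo[r], hi = keep_hi[r];
    int rp = ref_starts[r];   // 1-based doubled frame
    int qp = 0;               // 0-based read offset

    size_t ci = 0;
    while (ci < cig.size()) {
      int len = 0;
      while (ci < cig.size() && isdigit(cig[ci])) {
        len = len * 10 + (cig[ci] - '0');
        ++ci;
      }
      char op = cig[ci];
      ++ci;
      if (op == 'S') { qp += len; continue; }
      if (op == 'M') {
        for (int t = 0; t < len; ++t) {
          int pos = rp + t;
          if (pos >= lo && pos <= hi &&
              (int)qual[qp + t] - 33 >= min_q) {
            int b = base_code(seq[qp + t]);
            if (b >= 0) {
              int fold = ((pos - 1) % genome_len);
              counts(fold, b + (strand ? 5 : 0)) += 1;
            }
          }
        }
        rp += len; qp += len;
      } else if (op == 'D') {
        for (int t = 0; t < len; ++t) {
          int pos = rp + t;
          if (pos >= lo && pos <= hi) {
            int fold = ((pos - 1) % genome_len);
            counts(fold, 4 + (strand ? 5 : 0)) += 1;
          }
        }
        rp += len;
      } else if (op == 'I') {
        int anchor = rp - 1;  // inserted after this reference position
        bool ok = anchor >= lo && anchor <= hi;
        if (ok) {
          for (int t = 0; t < len; ++t) {
            if ((int)qual[qp + t] - 33 < min_q) { ok = false; break; }
          }
        }
        if (ok) {
          int fold = ((anchor - 1) % genome_len) + 1;
          ins_pos.push_back(fold);
          ins_seq.push_back(seq.substr(qp, len));
          ins_strand.push_back(strand);
        }
        qp += len;
      }
    }
  }
  return List::create(_["counts"] = counts,
                      _["ins_pos"] = wrap(ins_pos),
                      _["ins_seq"] = wrap(ins_seq),
                      _["ins_strand"] = wrap(ins_strand));
}

// Best semi-global edit distance of each read against any decoy (read
// global, decoy free at both ends), with a k-mer prefilter so reads that
// share no k-mer with any decoy are skipped (distance NA).
// [[Rcpp::export(name = ".numt_screen_cpp")]]
IntegerVector numt_screen_cpp(CharacterVector seqs, CharacterVector decoys,
                              int k) {
  // decoy k-mer set
  std::unordered_map<uint64_t, bool> kmers;
  std::vector<std::string> dec(decoys.size());
  for (int d = 0; d < decoys.size(); ++d) {
    dec[d] = as<std::string>(decoys[d]);
    for (int i = 0; i + k <= (int)dec[d].size(); ++i) {
      uint64_t code;
      if (encode_kmer(dec[d].c_str() + i, k, code)) kmers[code] = true;
    }
  }
  int n = seqs.size();
  IntegerVector out(n, NA_INTEGER);
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(seqs[r]);
    int m = read.size();
    bool hit = false;
    for (int i = 0; i + k <= m && !hit; i += k) {
      uint64_t code;
      if (encode_kmer(read.c_str() + i, k, code) && kmers.count(code)) {
        hit = true;
      }
    }
    if (!hit) continue;
    int best = m;
    for (auto& d : dec) {
      int w = d.size();
      std::vector<int> prev(w + 1, 0), cur(w + 1, 0);
      for (int i = 1; i <= m; ++i) {
        cur[0] = i;
        for (int j = 1; j <= w; ++j) {
          int sub = prev[j - 1] + (read[i - 1] == d[j - 1] ? 0 : 1);
          cur[j] = std::min({sub, prev[j] + 1, cur[j - 1] + 1});
        }
        std::swap(prev, cur);
      }
      int dmin = *std::min_element(prev.begin(), prev.end());
      best = std::min(best, dmin);
    }
    out[r] = best;
  }
  return out;
}
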