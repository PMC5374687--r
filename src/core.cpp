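#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// ---- sequence helpers -------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N and friends: match nothing
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G'; case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g'; case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    if (CharacterVector::is_na(x[i])) { out[i] = NA_STRING; continue; }
    out[i] = revcomp(as<std::string>(x[i]));
  }
  out.names() = x.names();
  return out;
}

// ---- k-mer index ------------------------------------------------------------
// Hash of every forward k-mer of the database to its (sequence, position)
// occurrences.  Reverse-strand matches are found at query time by also looking
// up the reverse complement of the query k-mer, which is equivalent to
// indexing both strands.

struct KmerHash {
  int k;
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> map; // 0-based pos
};

static bool encode_kmer(const char* s, int k, uint64_t& code) {
  code = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// [[Rcpp::export]]
SEXP cpp_kmer_index_build(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<KmerHash> xp(new KmerHash(), true);
  xp->k = k;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) continue; // caller warns
    for (int p = 0; p + k <= (int)s.size(); ++p) {
      uint64_t code;
      if (encode_kmer(s.c_str() + p, k, code))
        xp->map[code].push_back(std::make_pair(i, p));
    }
  }
  return xp;
}

// enumerate all codes within Hamming distance r of `kmer` (N positions are
// forced substitutions that consume mismatch budget); call f(code, mism)
template <typename F>
static void enum_neighbors(const std::string& kmer, int r, F f) {
  int k = kmer.size();
  std::vector<int> npos; // positions holding N
  uint64_t base = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(kmer[i]);
    if (b < 0) { npos.push_back(i); b = 0; }
    base = (base << 2) | (uint64_t)b;
  }
  if ((int)npos.size() > r) return;
  int forced = npos.size();
  // substitute forced positions over all 4 bases, then free mismatches
  std::vector<uint64_t> seeds;
  seeds.push_back(base);
  for (int np : npos) {
    std::vector<uint64_t> next;
    int shift = 2 * (k - 1 - np);
    for (uint64_t s : seeds)
      for (uint64_t b = 0; b < 4; ++b)
        next.push_back((s & ~(3ULL << shift)) | (b << shift));
    seeds = next;
  }
  int free_r = r - forced;
  for (uint64_t s : seeds) {
    f(s, forced);
    if (free_r >= 1) {
      for (int i = 0; i < k; ++i) {
        bool skip = false;
        for (int np : npos) if (np == i) { skip = true; break; }
        if (skip) continue;
        int sh = 2 * (k - 1 - i);
        uint64_t orig = (s >> sh) & 3ULL;
        for (uint64_t b = 0; b < 4; ++b) {
          if (b == orig) continue;
          uint64_t c1 = (s & ~(3ULL << sh)) | (b << sh);
          f(c1, forced + 1);
          if (free_r >= 2) {
            for (int j = i + 1; j < k; ++j) {
              bool skip2 = false;
              for (int np : npos) if (np == j) { skip2 = true; break; }
              if (skip2) continue;
              int sh2 = 2 * (k - 1 - j);
              uint64_t orig2 = (c1 >> sh2) & 3ULL;
              for (uint64_t b2 = 0; b2 < 4; ++b2) {
                if (b2 == orig2) continue;
                f((c1 & ~(3ULL << sh2)) | (b2 << sh2), forced + 2);
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_kmer_index_lookup(SEXP xp_, std::string kmer, int r) {
  XPtr<KmerHash> xp(xp_);
  int k = xp->k;
  if ((int)kmer.size() != k) stop("query k-mer length must equal index k");
  std::vector<int> seq_out, pos_out, mm_out;
  std::vector<std::string> strand_out;
  for (int strand = 0; strand < 2; ++strand) {
    std::string q = strand == 0 ? kmer : revcomp(kmer);
    enum_neighbors(q, r, [&](uint64_t code, int mism) {
      auto it = xp->map.find(code);
      if (it == xp->map.end()) return;
      for (auto& occ : it->second) {
        seq_out.push_back(occ.first + 1);
        pos_out.push_back(occ.second + 1);
        strand_out.push_back(strand == 0 ? "+" : "-");
        mm_out.push_back(mism);
      }
    });
  }
  return DataFrame::create(_["seq"] = seq_out, _["pos"] = pos_out,
                           _["strand"] = strand_out, _["mismatches"] = mm_out,
                           _["stringsAsFactors"] = false);
}

static bool screen_one(const std::string& read, KmerHash* idx, int r, int s) {
  int k = idx->k;
  int len = read.size();
  if (len < k) return false;
  std::vector<int> starts;
  for (int p = 0; p + k <= len; p += s) starts.push_back(p);
  if (starts.empty() || starts.back() != len - k) starts.push_back(len - k);
  for (int p : starts) {
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = read.substr(p, k);
      if (strand == 1) q = revcomp(q);
      bool hit = false;
      enum_neighbors(q, r, [&](uint64_t code, int) {
        if (!hit && idx->map.count(code)) hit = true;
      });
      if (hit) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
LogicalVector cpp_screen_pairs(SEXP xp_, CharacterVector seq1, CharacterVector seq2,
                               int r, int s) {
  XPtr<KmerHash> xp(xp_);
  int n = seq1.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(seq1[i]);
    bool hit = screen_one(a, xp, r, s);
    if (!hit) {
      std::string b = as<std::string>(seq2[i]);
      hit = screen_one(b, xp, r, s);
    }
    out[i] = hit;
  }
  return out;
}

// ---- Gotoh local alignment --------------------------------------------------
// Affine gaps: a gap of length L costs gap_open + L * gap_extend (penalties
// supplied as negative scores).  N matches nothing.

struct Aln {
  int score, qs, qe, ss, se, matches, length; // 1-based closed, 0 score = none
};

static Aln gotoh_local(const std::string& q, const std::string& s,
                       int match, int mismatch, int gap_open, int gap_extend) {
  int m = q.size(), n = s.size();
  Aln best; best.score = 0; best.qs = best.qe = best.ss = best.se = 0;
  best.matches = 0; best.length = 0;
  if (m == 0 || n == 0) return best;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), 0),
                   F((m + 1) * (n + 1), 0);
  std::vector<unsigned char> TH((m + 1) * (n + 1), 0), TE((m + 1) * (n + 1), 0),
                             TF((m + 1) * (n + 1), 0);
  // TH: 0 stop, 1 diag, 2 from E (gap in query / consume subject), 3 from F
  int bi = 0, bj = 0, bscore = 0;
  const int NEG = -1000000000;
  for (int i = 0; i <= m; ++i) { E[i * (n + 1)] = NEG; }
  for (int j = 0; j <= n; ++j) { F[j] = NEG; }
  for (int i = 1; i <= m; ++i) {
    int bq = base_code(q[i - 1]);
    for (int j = 1; j <= n; ++j) {
      int idx = i * (n + 1) + j;
      int openE = H[idx - 1] + gap_open + gap_extend;
      int extE  = E[idx - 1] + gap_extend;
      if (openE >= extE) { E[idx] = openE; TE[idx] = 0; } else { E[idx] = extE; TE[idx] = 1; }
      int up = idx - (n + 1);
      int openF = H[up] + gap_open + gap_extend;
      int extF  = F[up] + gap_extend;
      if (openF >= extF) { F[idx] = openF; TF[idx] = 0; } else { F[idx] = extF; TF[idx] = 1; }
      int bs = base_code(s[j - 1]);
      int sub = (bq >= 0 && bq == bs) ? match : mismatch;
      int diag = H[up - 1] + sub;
      int h = 0; unsigned char t = 0;
      if (diag > h) { h = diag; t = 1; }
      if (E[idx] > h) { h = E[idx]; t = 2; }
      if (F[idx] > h) { h = F[idx]; t = 3; }
      H[idx] = h; TH[idx] = t;
      if (h > bscore) { bscore = h; bi = i; bj = j; }
    }
  }
  if (bscore <= 0) return best;
  // traceback
  int i = bi, j = bj, matches = 0, length = 0;
  int state = 0; // 0 = in H, 1 = in E, 2 = in F
  while (i > 0 && j > 0) {
    int idx = i * (n + 1) + j;
    if (state == 0) {
      unsigned char t = TH[idx];
      if (t == 0) break;
      if (t == 1) {
        int bq = base_code(q[i - 1]), bs = base_code(s[j - 1]);
        if (bq >= 0 && bq == bs) ++matches;
        ++length; --i; --j;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ++length;
      if (TE[idx] == 0) state = 0;
      --j;
    } else {
      ++length;
      if (TF[idx] == 0) state = 0;
      --i;
    }
  }
  best.score = bscore;
  best.qs = i + 1; best.qe = bi;
  best.ss = j + 1; best.se = bj;
  best.matches = matches; best.length = length;
  return best;
}

// [[Rcpp::export]]
List cpp_smith_waterman(std::string query, std::string subject,
                        int match, int mismatch, int gap_open, int gap_extend) {
  Aln a = gotoh_local(query, subject, match, mismatch, gap_open, gap_extend);
  return List::create(_["score"] = a.score, _["qstart"] = a.qs, _["qend"] = a.qe,
                      _["sstart"] = a.ss, _["send"] = a.se,
                      _["matches"] = a.matches, _["length"] = a.length);
}

// ---- seed-and-extend local alignment ---------------------------------------
// For each query (both strands), exact `word`-mer seed hits against the
// forward strand of every subject are chained by diagonal proximity; each
// chain defines a subject window in which a full Gotoh local alignment is
// computed.  Coordinates are reported 1-based closed on the forward query.

// [[Rcpp::export]]
DataFrame cpp_local_align(CharacterVector queries, CharacterVector subjects,
                          int word, int match, int mismatch,
                          int gap_open, int gap_extend, int min_len) {
  int ns = subjects.size();
  std::vector<std::string> subj(ns);
  for (int i = 0; i < ns; ++i) subj[i] = as<std::string>(subjects[i]);
  // word hash over subjects
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> hash;
  for (int si = 0; si < ns; ++si) {
    const std::string& s = subj[si];
    for (int p = 0; p + word <= (int)s.size(); ++p) {
      uint64_t code;
      if (encode_kmer(s.c_str() + p, word, code))
        hash[code].push_back(std::make_pair(si, p));
    }
  }
  std::vector<int> o_query, o_qs, o_qe, o_subj, o_ss, o_se, o_score, o_match, o_len;
  std::vector<std::string> o_strand;
  struct Seed { int subj, qpos, spos; };
  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string fwd = as<std::string>(queries[qi]);
    int qlen = fwd.size();
    if (qlen < word) continue;
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? fwd : revcomp(fwd);
      std::vector<Seed> seeds;
      for (int p = 0; p + word <= qlen; ++p) {
        uint64_t code;
        if (!encode_kmer(q.c_str() + p, word, code)) continue;
        auto it = hash.find(code);
        if (it == hash.end()) continue;
        for (auto& occ : it->second)
          seeds.push_back({occ.first, p, occ.second});
      }
      if (seeds.empty()) continue;
      std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
        if (a.subj != b.subj) return a.subj < b.subj;
        int da = a.spos - a.qpos, db = b.spos - b.qpos;
        if (da != db) return da < db;
        return a.spos < b.spos;
      });
      // chain seeds: same subject, diagonal within 15, subject gap <= qlen
      size_t i0 = 0;
      std::vector<std::pair<int,std::pair<int,int>>> windows; // subj -> [lo,hi)
      while (i0 < seeds.size()) {
        size_t i1 = i0 + 1;
        int lo = seeds[i0].spos, hi = seeds[i0].spos + word;
        while (i1 < seeds.size() && seeds[i1].subj == seeds[i0].subj) {
          int dprev = seeds[i1 - 1].spos - seeds[i1 - 1].qpos;
          int dcur  = seeds[i1].spos - seeds[i1].qpos;
          if (dcur - dprev > 15 || seeds[i1].spos - (hi - word) > qlen) break;
          hi = std::max(hi, seeds[i1].spos + word);
          lo = std::min(lo, seeds[i1].spos);
          ++i1;
        }
        int slen = subj[seeds[i0].subj].size();
        int wlo = std::max(0, lo - qlen - 15);
        int whi = std::min(slen, hi + qlen + 15);
        windows.push_back({seeds[i0].subj, {wlo, whi}});
        i0 = i1;
      }
      // merge overlapping windows on the same subject
      std::sort(windows.begin(), windows.end());
      std::vector<std::pair<int,std::pair<int,int>>> merged;
      for (auto& w : windows) {
        if (!merged.empty() && merged.back().first == w.first &&
            w.second.first <= merged.back().second.second) {
          merged.back().second.second =
            std::max(merged.back().second.second, w.second.second);
        } else merged.push_back(w);
      }
      for (auto& w : merged) {
        int si = w.first, wlo = w.second.first, whi = w.second.second;
        std::string win = subj[si].substr(wlo, whi - wlo);
        // Waterman-Eggert style: report successive non-overlapping local
        // alignments by masking each reported subject span, so tied
        // placements of a repeated query within one window all surface
        for (int iter = 0; iter < 8; ++iter) {
          Aln a = gotoh_local(q, win, match, mismatch, gap_open, gap_extend);
          if (a.score <= 0 || a.length < min_len) break;
          int qs_f, qe_f;
          if (strand == 0) { qs_f = a.qs; qe_f = a.qe; }
          else { qs_f = qlen - a.qe + 1; qe_f = qlen - a.qs + 1; }
          o_query.push_back(qi + 1);
          o_qs.push_back(qs_f); o_qe.push_back(qe_f);
          o_subj.push_back(si + 1);
          o_ss.push_back(wlo + a.ss); o_se.push_back(wlo + a.se);
          o_strand.push_back(strand == 0 ? "+" : "-");
          o_score.push_back(a.score);
          o_match.push_back(a.matches);
          o_len.push_back(a.length);
          for (int p = a.ss - 1; p < a.se; ++p) win[p] = 'N';
        }
      }
    }
  }
  return DataFrame::create(_["query"] = o_query, _["qstart"] = o_qs, _["qend"] = o_qe,
                           _["subject"] = o_subj, _["sstart"] = o_ss, _["send"] = o_se,
                           _["strand"] = o_strand, _["score"] = o_score,
                           _["matches"] = o_match, _["length"] = o_len,
                           _["stringsAsFactors"] = false);
}

// ---- ungapped overlap scoring for consensus assembly ------------------------
// Best ungapped overlap between suffix of a and prefix of b (offset >= 0 means
// b starts `offset` columns after a's start).  Returns best offset by matches.

// [[Rcpp::export]]
List cpp_best_overlap(std::string a, std::string b, int min_overlap) {
  int la = a.size(), lb = b.size();
  int best_off = NA_INTEGER, best_matches = -1, best_ov = 0;
  for (int off = -(lb - min_overlap); off <= la - min_overlap; ++off) {
    int start = std::max(0, off);
    int end = std::min(la, off + lb);
    int ov = end - start;
    if (ov < min_overlap) continue;
    int matches = 0;
    for (int i = start; i < end; ++i) {
      int ca = base_code(a[i]), cb = base_code(b[i - off]);
      if (ca >= 0 && ca == cb) ++matches;
    }
    if (matches > best_matches) {
      best_matches = matches; best_off = off; best_ov = ov;
    }
  }
  return List::create(_["offset"] = best_off, _["overlap"] = best_ov,
                      _["matches"] = best_matches);
}
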