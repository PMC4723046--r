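#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

static inline char compbase(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  case 'N': return 'N';
  case '-': return '-';
  }
  return 'N';
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = compbase(s[i]);
  return out;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

// [[Rcpp::export]]
int cpp_count_mismatch(std::string a, std::string b) {
  if (a.size() != b.size()) stop("strings differ in length");
  int mm = 0;
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++mm;
  return mm;
}

typedef std::unordered_map<uint64_t, std::vector<int> > kindex_t;

// hash of k-mer at position p of s; returns false if any non-ACGT base
static inline bool kmer_hash(const std::string& s, int p, int k, uint64_t& h) {
  h = 0;
  for (int t = 0; t < k; ++t) {
    int b = base2bit(s[p + t]);
    if (b < 0) return false;
    h = (h << 2) | (uint64_t)b;
  }
  return true;
}

static void build_index(const std::string& s, int k, int max_pos, kindex_t& idx) {
  uint64_t h;
  int last = std::min((int)s.size() - k, max_pos - 1);
  for (int p = 0; p <= last; ++p)
    if (kmer_hash(s, p, k, h)) idx[h].push_back(p);
}

struct AlnResult {
  bool ok;
  int start;      // on extended target
  int span;       // reference bases consumed
  int matches;
  int cols;
  double ident;
  std::string proj, pq, ins;
};

// Fitting alignment: query global, free end gaps on target.
// match +1, mismatch -2, gap -3. Traceback gives reference-projected read.
static AlnResult fit_align(const std::string& q, const std::string& qual,
                           const std::string& T, int ws, int we) {
  AlnResult res; res.ok = false;
  int m = q.size(), n = we - ws;
  if (n <= 0 || (double)m * n > 8e6) return res;
  const int MATCH = 1, MISM = -2, GAP = -3;
  std::vector<int> S((m + 1) * (n + 1));
  std::vector<char> D((m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) { S[j] = 0; D[j] = 0; }
  for (int i = 1; i <= m; ++i) {
    S[i * (n + 1)] = i * GAP;
    D[i * (n + 1)] = 'U';
  }
  for (int i = 1; i <= m; ++i) {
    int* Sr = &S[i * (n + 1)];
    int* Sp = &S[(i - 1) * (n + 1)];
    char* Dr = &D[i * (n + 1)];
    char qc = q[i - 1];
    for (int j = 1; j <= n; ++j) {
      int sc = Sp[j - 1] + (qc == T[ws + j - 1] ? MATCH : MISM);
      char d = 'M';
      int up = Sp[j] + GAP;
      if (up > sc) { sc = up; d = 'U'; }
      int lf = Sr[j - 1] + GAP;
      if (lf > sc) { sc = lf; d = 'L'; }
      Sr[j] = sc; Dr[j] = d;
    }
  }
  // best over final row, smallest j on tie (leftmost end)
  int bj = 0, bs = S[m * (n + 1)];
  for (int j = 1; j <= n; ++j)
    if (S[m * (n + 1) + j] > bs) { bs = S[m * (n + 1) + j]; bj = j; }
  if (bj == 0) return res;
  // traceback
  std::string proj, pq, ins;
  std::vector<std::string> ins_parts;
  int i = m, j = bj, matches = 0, cols = 0;
  std::string cur_ins_seq, cur_ins_q;
  while (i > 0 && j > 0) {
    char d = D[i * (n + 1) + j];
    if (d == 'M') {
      if (!cur_ins_seq.empty()) {
        std::reverse(cur_ins_seq.begin(), cur_ins_seq.end());
        std::reverse(cur_ins_q.begin(), cur_ins_q.end());
        ins_parts.push_back(std::to_string(ws + j) + ":" + cur_ins_seq + ":" + cur_ins_q);
        cur_ins_seq.clear(); cur_ins_q.clear();
      }
      proj.push_back(q[i - 1]); pq.push_back(qual[i - 1]);
      if (q[i - 1] == T[ws + j - 1]) ++matches;
      ++cols; --i; --j;
    } else if (d == 'U') {         // read base not in reference: insertion
      cur_ins_seq.push_back(q[i - 1]); cur_ins_q.push_back(qual[i - 1]);
      ++cols; --i;
    } else {                        // reference base skipped: deletion
      proj.push_back('-');
      pq.push_back(i > 0 ? qual[i - 1] : qual[0]);
      ++cols; --j;
    }
  }
  if (i > 0) return res;            // leading query gap: reject placement
  if (!cur_ins_seq.empty()) {
    std::reverse(cur_ins_seq.begin(), cur_ins_seq.end());
    std::reverse(cur_ins_q.begin(), cur_ins_q.end());
    ins_parts.push_back(std::to_string(ws + j) + ":" + cur_ins_seq + ":" + cur_ins_q);
  }
  std::reverse(proj.begin(), proj.end());
  std::reverse(pq.begin(), pq.end());
  for (int t = (int)ins_parts.size() - 1; t >= 0; --t) {
    if (!ins.empty()) ins += ";";
    ins += ins_parts[t];
  }
  res.ok = true;
  res.start = ws + j;
  res.span = (int)proj.size();
  res.matches = matches;
  res.cols = cols;
  res.ident = cols > 0 ? (double)matches / cols : 0.0;
  res.proj = proj; res.pq = pq; res.ins = ins;
  return res;
}

struct Cand { long long diag; int strand; int votes; };

// Map reads against a (possibly circular) reference with a two-threshold
// acceptance predicate: aligned read fraction >= min_frac and identity
// >= min_ident.  Best placement by identity, tie -> leftmost start, then
// forward strand.  Returns one row per accepted read.
// [[Rcpp::export]]
List cpp_map_reads(std::string ref, CharacterVector reads, CharacterVector quals,
                   int k, int stride, double min_frac, double min_ident,
                   bool circular, int max_cand, int max_occ) {
  int L = ref.size();
  int maxread = 0;
  for (int i = 0; i < reads.size(); ++i)
    maxread = std::max(maxread, (int)strlen(reads[i]));
  int band_max = std::max(8, maxread / 10);
  std::string T = ref;
  if (circular && L > k)
    T += ref.substr(0, std::min(L, maxread + band_max + 8));
  kindex_t idx;
  build_index(T, k, L, idx);

  std::vector<int> o_read, o_start, o_end, o_matches, o_cols;
  std::vector<double> o_ident, o_frac;
  std::vector<std::string> o_strand, o_proj, o_pq, o_ins;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    std::string fq = as<std::string>(quals[r]);
    int m = fwd.size();
    if (m < k || m == 0) continue;
    int band = std::max(8, m / 10);
    std::string rev = revcomp_str(fwd);
    std::string rq(fq.rbegin(), fq.rend());
    std::unordered_map<long long, int> votes;
    for (int s = 0; s < 2; ++s) {
      const std::string& sq = (s == 0) ? fwd : rev;
      for (int off = 0; off <= m - k; off += stride) {
        int o2 = (off + stride > m - k && off != m - k) ? m - k : off;
        uint64_t h;
        if (!kmer_hash(sq, o2, k, h)) continue;
        kindex_t::iterator it = idx.find(h);
        if (it == idx.end()) continue;
        const std::vector<int>& pos = it->second;
        if ((int)pos.size() > max_occ) continue;
        for (size_t t = 0; t < pos.size(); ++t) {
          long long diag = (long long)pos[t] - o2;
          if (diag < -(long long)band || diag >= L) continue;
          votes[(diag << 1) | s] += 1;
        }
        if (o2 == m - k) break;
      }
    }
    if (votes.empty()) continue;
    std::vector<Cand> cands;
    for (std::unordered_map<long long, int>::iterator it = votes.begin();
         it != votes.end(); ++it)
      cands.push_back(Cand{it->first >> 1, (int)(it->first & 1), it->second});
    std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
      if (a.votes != b.votes) return a.votes > b.votes;
      if (a.diag != b.diag) return a.diag < b.diag;
      return a.strand < b.strand;
    });
    // drop candidates within band of a stronger same-strand candidate
    std::vector<Cand> kept;
    for (size_t c = 0; c < cands.size() && (int)kept.size() < max_cand; ++c) {
      bool dup = false;
      for (size_t u = 0; u < kept.size(); ++u)
        if (kept[u].strand == cands[c].strand &&
            std::llabs(kept[u].diag - cands[c].diag) <= band) { dup = true; break; }
      if (!dup) kept.push_back(cands[c]);
    }
    bool have = false;
    AlnResult best; int best_strand = 0; int best_startL = 0;
    for (size_t c = 0; c < kept.size(); ++c) {
      const std::string& sq = (kept[c].strand == 0) ? fwd : rev;
      const std::string& sql = (kept[c].strand == 0) ? fq : rq;
      long long diag = kept[c].diag;
      AlnResult res; res.ok = false;
      if (diag >= 0 && diag + m <= (long long)T.size()) {
        int mm = 0;
        for (int t = 0; t < m; ++t) if (sq[t] != T[diag + t]) ++mm;
        double ident = (double)(m - mm) / m;
        if (ident >= min_ident) {
          res.ok = true; res.start = (int)diag; res.span = m;
          res.matches = m - mm; res.cols = m; res.ident = ident;
          res.proj = sq; res.pq = sql; res.ins = "";
        }
      }
      if (!res.ok) {
        int ws = std::max(0, (int)diag - band);
        int we = std::min((int)T.size(), (int)diag + m + band);
        res = fit_align(sq, sql, T, ws, we);
        if (res.ok && res.ident < min_ident) res.ok = false;
      }
      if (!res.ok) continue;
      double frac = 1.0;  // query-global alignment: whole read aligned
      if (frac < min_frac) continue;
      int startL = res.start % L;
      if (!have || res.ident > best.ident ||
          (res.ident == best.ident && (startL < best_startL ||
           (startL == best_startL && kept[c].strand < best_strand)))) {
        have = true; best = res; best_strand = kept[c].strand; best_startL = startL;
      }
    }
    if (!have) continue;
    o_read.push_back(r + 1);
    o_start.push_back(best_startL);
    o_end.push_back(best_startL + best.span);
    o_strand.push_back(best_strand == 0 ? "+" : "-");
    o_ident.push_back(best.ident);
    o_frac.push_back(1.0);
    o_matches.push_back(best.matches);
    o_cols.push_back(best.cols);
    o_proj.push_back(best.proj);
    o_pq.push_back(best.pq);
    // rebase insertion coordinates onto [0, L)
    if (best.ins.empty()) { o_ins.push_back(""); }
    else {
      std::string out;
      size_t p = 0;
      while (p < best.ins.size()) {
        size_t e = best.ins.find(';', p);
        if (e == std::string::npos) e = best.ins.size();
        std::string part = best.ins.substr(p, e - p);
        size_t c1 = part.find(':');
        long long pos = 0;
        for (size_t t = 0; t < c1; ++t) pos = pos * 10 + (part[t] - '0');
        pos %= L;
        if (!out.empty()) out += ";";
        out += std::to_string(pos) + part.substr(c1);
        p = e + 1;
      }
      o_ins.push_back(out);
    }
  }
  return List::create(
    _["read"] = wrap(o_read), _["start"] = wrap(o_start), _["end"] = wrap(o_end),
    _["strand"] = wrap(o_strand), _["identity"] = wrap(o_ident),
    _["frac"] = wrap(o_frac), _["matches"] = wrap(o_matches),
    _["cols"] = wrap(o_cols), _["proj"] = wrap(o_proj), _["pqual"] = wrap(o_pq),
    _["ins"] = wrap(o_ins));
}

// Per-base tallies of reference-projected reads.  Rows: A, C, G, T, '-'.
// Bases with Phred quality (+33 encoded) below min_qual are skipped.
// [[Rcpp::export]]
List cpp_pileup(int L, IntegerVector starts, CharacterVector proj,
                CharacterVector pqual, int min_qual) {
  IntegerMatrix counts(5, L);
  NumericMatrix qsum(5, L);
  for (int r = 0; r < proj.size(); ++r) {
    const char* s = proj[r];
    const char* q = pqual[r];
    int n = strlen(s);
    int st = starts[r];
    for (int t = 0; t < n; ++t) {
      int row;
      switch (s[t]) {
      case 'A': row = 0; break; case 'C': row = 1; break;
      case 'G': row = 2; break; case 'T': row = 3; break;
      case '-': row = 4; break; default: row = -1;
      }
      if (row < 0) continue;
      int qv = (int)q[t] - 33;
      if (qv < min_qual) continue;
      int pos = (st + t) % L;
      counts(row, pos) += 1;
      qsum(row, pos) += qv;
    }
  }
  return List::create(_["counts"] = counts, _["qsum"] = qsum);
}

// All seed pairs (i, j), i < j, where s[i..i+k) == revcomp(s[j..j+k)).
// K-mers occurring more than max_occ times are skipped.
// [[Rcpp::export]]
List cpp_ir_seeds(std::string s, int k, int max_occ) {
  int L = s.size();
  kindex_t idx;
  build_index(s, k, L, idx);
  std::string rc = revcomp_str(s);
  std::vector<int> vi, vj;
  uint64_t h;
  for (int x = 0; x + k <= L; ++x) {
    // revcomp of s[x..x+k) is rc[L-x-k..L-x)
    if (!kmer_hash(rc, L - x - k, k, h)) continue;
    kindex_t::iterator it = idx.find(h);
    if (it == idx.end()) continue;
    const std::vector<int>& pos = it->second;
    if ((int)pos.size() > max_occ) continue;
    for (size_t t = 0; t < pos.size(); ++t) {
      if (pos[t] < x) { vi.push_back(pos[t]); vj.push_back(x); }
      if (vi.size() > 8000000) stop("too many inverted-repeat seed pairs");
    }
  }
  return List::create(_["i"] = wrap(vi), _["j"] = wrap(vj));
}

// Longest suffix(a)/prefix(b) overlap >= min_overlap with mismatch rate
// <= max_mm_frac, anchored by an exact match of b's first k bases in a.
// Returns c(overlap, mismatches) or c(-1, -1).
// [[Rcpp::export]]
IntegerVector cpp_find_overlap(std::string a, std::string b, int k,
                               int min_overlap, int max_ov, double max_mm_frac) {
  int la = a.size(), lb = b.size();
  IntegerVector out = IntegerVector::create(-1, -1);
  if (la < min_overlap || lb < std::min(min_overlap, k)) return out;
  std::string seed = b.substr(0, std::min(k, lb));
  size_t p = a.find(seed);
  while (p != std::string::npos) {
    int ov = la - (int)p;
    if (ov >= min_overlap && ov <= max_ov && ov <= lb) {
      int mm = 0;
      for (int t = 0; t < ov; ++t) if (a[p + t] != b[t]) ++mm;
      if (mm <= max_mm_frac * ov) {
        if (ov > out[0]) { out[0] = ov; out[1] = mm; }
      }
    }
    p = a.find(seed, p + 1);
  }
  return out;
}
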