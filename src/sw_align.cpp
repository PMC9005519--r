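#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman / Gotoh) with soft-clipped
// ends. A gap of length k costs gap_open + k * gap_extend (BWA-style).
// 'N' never scores as a match. Ties among equal-score cells resolve to the
// smallest reference end coordinate, then the smallest query end; during
// traceback gap runs are extended in preference to being re-opened, which
// left-shifts INDELs.

static const int NEG = -(1 << 28);

struct AlnResult {
  bool hit;
  int score;      // raw H score minus clip penalty
  int ref_start;  // 0-based
  int qstart, qend; // 0-based half-open on the oriented query
  std::string cigar;
};

static inline int subst(char q, char r, int match, int mismatch) {
  if (q == r && q != 'N') return match;
  return -mismatch;
}

static std::string rc(const std::string& s) {
  std::string out(s.rbegin(), s.rend());
  for (char& c : out) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default: c = 'N';
    }
  }
  return out;
}

static void push_op(std::vector<std::pair<char,int> >& ops, char op) {
  if (!ops.empty() && ops.back().first == op) ops.back().second++;
  else ops.push_back(std::make_pair(op, 1));
}

static AlnResult sw_one(const std::string& q, const std::string& r,
                        int match, int mismatch, int go, int ge,
                        int clip_pen) {
  const int n = (int)q.size(), m = (int)r.size();
  AlnResult res; res.hit = false; res.score = NEG;

  // exact-substring fast path: a full-length exact match achieves the
  // global maximum score n*match, and find() returns the smallest start
  // (hence smallest end) occurrence
  if (q.find('N') == std::string::npos) {
    size_t pos = r.find(q);
    if (pos != std::string::npos) {
      res.hit = true;
      res.score = n * match;
      res.ref_start = (int)pos;
      res.qstart = 0; res.qend = n;
      res.cigar = std::to_string(n) + "M";
      return res;
    }
  }

  std::vector<int> H((size_t)(n + 1) * (m + 1), 0);
  std::vector<int> Ix((size_t)(n + 1) * (m + 1), NEG); // gap in ref ('I')
  std::vector<int> Iy((size_t)(n + 1) * (m + 1), NEG); // gap in query ('D')
  const int W = m + 1;

  int best = 0, bi = -1, bj = -1;
  for (int i = 1; i <= n; ++i) {
    const char qc = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const size_t c = (size_t)i * W + j;
      int Mv = H[c - W - 1] + subst(qc, r[j - 1], match, mismatch);
      int ix = std::max(H[c - W] - go - ge, Ix[c - W] - ge);
      int iy = std::max(H[c - 1] - go - ge, Iy[c - 1] - ge);
      Ix[c] = ix; Iy[c] = iy;
      int h = Mv;
      if (ix > h) h = ix;
      if (iy > h) h = iy;
      if (h < 0) h = 0;
      H[c] = h;
      // strictly-greater keeps the first (smallest j, then i) best cell
      // when scanning j within i; compare j first across rows
      if (h > best || (h == best && bi >= 0 &&
                       (j < bj || (j == bj && i < bi)))) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
  }
  if (bi < 0 || best <= 0) return res;

  // traceback
  std::vector<std::pair<char,int> > ops;
  int i = bi, j = bj;
  // state: 0 = H(match), 1 = Ix('I'), 2 = Iy('D')
  int state;
  {
    const size_t c = (size_t)i * W + j;
    if (H[c] == H[c - W - 1] + subst(q[i - 1], r[j - 1], match, mismatch))
      state = 0;
    else if (H[c] == Iy[c]) state = 2;
    else state = 1;
  }
  while (i > 0 && j > 0) {
    const size_t c = (size_t)i * W + j;
    if (H[c] == 0 && state == 0) break;
    if (state == 0) {
      push_op(ops, 'M');
      --i; --j;
      const size_t p = (size_t)i * W + j;
      if (H[p] == 0) break;
      if (i > 0 && j > 0 &&
          H[p] == H[p - W - 1] + subst(q[i - 1], r[j - 1], match, mismatch))
        state = 0;
      else if (H[p] == Iy[p]) state = 2;
      else if (H[p] == Ix[p]) state = 1;
      else state = 0; // H==0 handled next loop
    } else if (state == 1) { // 'I': consumes query
      push_op(ops, 'I');
      const size_t c2 = (size_t)i * W + j;
      bool ext = (Ix[c2] == Ix[c2 - W] - ge); // prefer extension (left-shift)
      --i;
      state = ext ? 1 : 0;
    } else { // 'D': consumes ref
      push_op(ops, 'D');
      const size_t c2 = (size_t)i * W + j;
      bool ext = (Iy[c2] == Iy[c2 - 1] - ge);
      --j;
      state = ext ? 2 : 0;
    }
  }

  res.hit = true;
  res.qstart = i; res.qend = bi;
  res.ref_start = j;
  std::reverse(ops.begin(), ops.end());
  std::string cig;
  if (i > 0) cig += std::to_string(i) + "S";
  for (size_t k = 0; k < ops.size(); ++k)
    cig += std::to_string(ops[k].second) + ops[k].first;
  if (n - bi > 0) cig += std::to_string(n - bi) + "S";
  res.cigar = cig;
  res.score = best - clip_pen * (i + (n - bi));
  return res;
}

// [[Rcpp::export(name = ".sw_align_batch")]]
DataFrame sw_align_batch(CharacterVector queries, std::string ref,
                         int match, int mismatch, int gap_open,
                         int gap_extend, int clip_penalty, int min_score,
                         bool both_strands = true) {
  const int nq = queries.size();
  IntegerVector score(nq), ref_start(nq), qstart(nq), qend(nq);
  CharacterVector strand(nq), cigar(nq);
  for (int k = 0; k < nq; ++k) {
    std::string q = as<std::string>(queries[k]);
    AlnResult plus = sw_one(q, ref, match, mismatch, gap_open, gap_extend,
                            clip_penalty);
    AlnResult minus; minus.hit = false; minus.score = NEG;
    if (both_strands) {
      std::string qr = rc(q);
      minus = sw_one(qr, ref, match, mismatch, gap_open, gap_extend,
                     clip_penalty);
    }
    const AlnResult* bestr = NULL;
    bool is_minus = false;
    if (plus.hit && (!minus.hit || plus.score >= minus.score)) {
      bestr = &plus;
    } else if (minus.hit) {
      bestr = &minus; is_minus = true;
    }
    if (bestr == NULL || bestr->score < min_score) {
      score[k] = NA_INTEGER; ref_start[k] = NA_INTEGER;
      qstart[k] = NA_INTEGER; qend[k] = NA_INTEGER;
      strand[k] = NA_STRING; cigar[k] = NA_STRING;
    } else {
      score[k] = bestr->score;
      ref_start[k] = bestr->ref_start;
      qstart[k] = bestr->qstart; qend[k] = bestr->qend;
      strand[k] = is_minus ? "-" : "+";
      cigar[k] = bestr->cigar;
    }
  }
  return DataFrame::create(
    _["score"] = score, _["ref_start"] = ref_start, _["strand"] = strand,
    _["cigar"] = cigar, _["qstart"] = qstart, _["qend"] = qend,
    _["stringsAsFactors"] = false);
}
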