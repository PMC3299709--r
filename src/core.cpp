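// Seed-and-extend alignment core: k-mer indexing, banded glocal (fitting)
// and banded local alignment with affine gaps, plus a 454-style error model.
// Coordinates are 0-based half-open throughout; conversion to 1-based happens
// only at the R I/O layer.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

static const double NEG_INF = -1e18;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string upper_seq(const std::string& s) {
  std::string r(s);
  for (char& c : r) c = (char) toupper((unsigned char) c);
  return r;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (char& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// ---------------------------------------------------------------------------
// K-mer index over a set of reference sequences
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  int step;
  std::vector<std::string> names;
  std::vector<std::string> seqs;   // uppercased
  // positions sorted by k-mer code for binary search
  std::vector<uint32_t> codes;
  std::vector<uint32_t> hit_seq;
  std::vector<uint32_t> hit_off;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k, int step) {
  if (k < 4 || k > 15) stop("k must be in [4, 15]");
  if (step < 1) stop("step must be >= 1");
  KmerIndex* idx = new KmerIndex();
  idx->k = k; idx->step = step;
  std::vector<std::pair<uint32_t, uint64_t>> recs;
  for (int s = 0; s < seqs.size(); ++s) {
    idx->names.push_back(as<std::string>(names[s]));
    std::string sq = upper_seq(as<std::string>(seqs[s]));
    idx->seqs.push_back(sq);
    int n = (int) sq.size();
    if (n < k) continue;
    for (int off = 0; off + k <= n; off += step) {
      uint32_t code = 0; bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = base_code(sq[off + j]);
        if (b < 0) { ok = false; break; }
        code = (code << 2) | (uint32_t) b;
      }
      if (ok) recs.push_back({code, ((uint64_t) s << 32) | (uint32_t) off});
    }
  }
  std::sort(recs.begin(), recs.end());
  idx->codes.reserve(recs.size());
  idx->hit_seq.reserve(recs.size());
  idx->hit_off.reserve(recs.size());
  for (auto& r : recs) {
    idx->codes.push_back(r.first);
    idx->hit_seq.push_back((uint32_t) (r.second >> 32));
    idx->hit_off.push_back((uint32_t) (r.second & 0xffffffffu));
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> idx(xp);
  IntegerVector lens(idx->seqs.size());
  for (size_t i = 0; i < idx->seqs.size(); ++i) lens[i] = (int) idx->seqs[i].size();
  return List::create(_["names"] = wrap(idx->names), _["lengths"] = lens,
                      _["k"] = idx->k, _["step"] = idx->step,
                      _["n_kmers"] = (double) idx->codes.size());
}

struct SeedBucket {
  int seqid;
  int diag;      // representative diagonal (ref_off - query_off)
  int count;
  int strand;    // 0 = forward, 1 = reverse-complement query
};

static void collect_buckets(const KmerIndex& idx, const std::string& q, int strand,
                            int seed_step, int max_per_kmer,
                            std::unordered_map<uint64_t, SeedBucket>& buckets) {
  int k = idx.k;
  int m = (int) q.size();
  if (m < k) return;
  for (int qp = 0; qp + k <= m; qp += seed_step) {
    uint32_t code = 0; bool ok = true;
    for (int j = 0; j < k; ++j) {
      int b = base_code(q[qp + j]);
      if (b < 0) { ok = false; break; }
      code = (code << 2) | (uint32_t) b;
    }
    if (!ok) continue;
    auto lo = std::lower_bound(idx.codes.begin(), idx.codes.end(), code);
    if (lo == idx.codes.end() || *lo != code) continue;
    auto hi = std::upper_bound(lo, idx.codes.end(), code);
    long n_hits = hi - lo;
    if (n_hits > max_per_kmer) n_hits = max_per_kmer;
    size_t i0 = lo - idx.codes.begin();
    for (long h = 0; h < n_hits; ++h) {
      int sid = (int) idx.hit_seq[i0 + h];
      int off = (int) idx.hit_off[i0 + h];
      int diag = off - qp;
      int bin = (diag + (1 << 28)) >> 5;
      uint64_t key = ((uint64_t) sid << 34) | ((uint64_t) strand << 33) | (uint64_t) bin;
      auto it = buckets.find(key);
      if (it == buckets.end()) {
        buckets[key] = {sid, diag, 1, strand};
      } else {
        it->second.count++;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Banded Gotoh alignment (fitting: whole query, free ref end-gaps)
// ---------------------------------------------------------------------------

struct AlnResult {
  bool ok = false;
  int ref_start = 0;      // within supplied window
  int matches = 0;
  int aln_ref_len = 0;
  std::string cigar;      // SAM-style, M/I/D (I = extra base in query)
  // events: type 1 = mismatch, 2 = insertion (in query), 3 = deletion
  std::vector<int> ev_type;
  std::vector<int> ev_refpos;  // window-relative, 0-based
  std::vector<int> ev_qpos;    // query 0-based (start of event)
  std::vector<int> ev_len;
  std::vector<std::string> ev_alt;
  double score = NEG_INF;
};

// Align full query q against window w with band around diagonal `doff`
// (expected w-position of q[0]).  match +1, mismatch -1, affine gap.
static AlnResult banded_fit(const std::string& q, const std::string& w, int doff,
                            int band, double gap_open, double gap_ext) {
  AlnResult res;
  int m = (int) q.size();
  int n = (int) w.size();
  if (m == 0 || n == 0) return res;
  int W = 2 * band + 1;
  // rows 0..m, band cells t in [0, W)
  std::vector<double> H((m + 1) * W, NEG_INF), E((m + 1) * W, NEG_INF), F((m + 1) * W, NEG_INF);
  std::vector<uint8_t> TH((m + 1) * W, 0), TE((m + 1) * W, 0), TF((m + 1) * W, 0);
  // TH: 0 diag, 1 from E, 2 from F, 3 start (free)
  auto centre = [&](int i) { return i + doff; };
  for (int t = 0; t < W; ++t) {
    int j = centre(0) + t - band;
    if (j >= 0 && j <= n) { H[t] = 0.0; TH[t] = 3; }
  }
  for (int i = 1; i <= m; ++i) {
    int ci = centre(i);
    char qc = q[i - 1];
    for (int t = 0; t < W; ++t) {
      int j = ci + t - band;
      size_t cell = (size_t) i * W + t;
      H[cell] = E[cell] = F[cell] = NEG_INF;
      if (j < 0 || j > n) continue;
      // E: gap in query (consumes ref), from (i, j-1) = same row t-1
      if (t - 1 >= 0 && j - 1 >= 0) {
        double openE = H[(size_t) i * W + (t - 1)] - gap_open - gap_ext;
        double extE  = E[(size_t) i * W + (t - 1)] - gap_ext;
        if (openE >= extE) { E[cell] = openE; TE[cell] = 0; }
        else { E[cell] = extE; TE[cell] = 1; }
      }
      // F: gap in ref (consumes query), from (i-1, j) = prev row t+1
      if (t + 1 < W) {
        double openF = H[(size_t) (i - 1) * W + (t + 1)] - gap_open - gap_ext;
        double extF  = F[(size_t) (i - 1) * W + (t + 1)] - gap_ext;
        if (openF >= extF) { F[cell] = openF; TF[cell] = 0; }
        else { F[cell] = extF; TF[cell] = 1; }
      }
      // H: diag from (i-1, j-1) = prev row t
      double best = NEG_INF; uint8_t tb = 0;
      if (j - 1 >= 0) {
        double dprev = H[(size_t) (i - 1) * W + t];
        if (dprev > NEG_INF / 2) {
          double sc = (base_code(qc) >= 0 && base_code(w[j - 1]) >= 0 &&
                       toupper((unsigned char) qc) == toupper((unsigned char) w[j - 1])) ? 1.0 : -1.0;
          best = dprev + sc; tb = 0;
        }
      }
      if (E[cell] > best) { best = E[cell]; tb = 1; }
      if (F[cell] > best) { best = F[cell]; tb = 2; }
      H[cell] = best; TH[cell] = tb;
    }
  }
  // best end in last row
  double bestScore = NEG_INF; int bestT = -1;
  for (int t = 0; t < W; ++t) {
    int j = centre(m) + t - band;
    if (j < 0 || j > n) continue;
    double v = H[(size_t) m * W + t];
    if (v > bestScore) { bestScore = v; bestT = t; }
  }
  if (bestT < 0 || bestScore <= NEG_INF / 2) return res;
  // traceback
  int i = m, t = bestT;
  int state = 0; // 0 = H, 1 = E, 2 = F
  std::string ops; // reversed op per column step: M/I/D (M covers match+mismatch)
  std::vector<char> mmflag; // parallel to ops for M: 1 if mismatch
  int matches = 0;
  while (i > 0) {
    size_t cell = (size_t) i * W + t;
    int j = centre(i) + t - band;
    if (state == 0) {
      uint8_t tb = TH[cell];
      if (tb == 3) break;
      if (tb == 0) {
        bool match = toupper((unsigned char) q[i - 1]) == toupper((unsigned char) w[j - 1]) &&
                     base_code(q[i - 1]) >= 0;
        ops.push_back('M'); mmflag.push_back(match ? 0 : 1);
        if (match) matches++;
        i -= 1; // t unchanged (diagonal)
      } else if (tb == 1) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D'); mmflag.push_back(0);
      uint8_t tb = TE[cell];
      t -= 1;
      state = (tb == 0) ? 0 : 1;
    } else {
      ops.push_back('I'); mmflag.push_back(0);
      uint8_t tb = TF[cell];
      i -= 1; t += 1;
      state = (tb == 0) ? 0 : 2;
    }
  }
  // i rows remain if traceback stopped early at free start (i == 0 normally)
  std::reverse(ops.begin(), ops.end());
  std::reverse(mmflag.begin(), mmflag.end());
  int jstart = centre(i) + t - band;
  res.ok = true;
  res.ref_start = jstart;
  res.matches = matches;
  res.score = bestScore;
  // build CIGAR + events
  std::string cig;
  int qp = i; // query position (0-based); should be 0
  int rp = jstart;
  size_t p = 0;
  while (p < ops.size()) {
    char op = ops[p]; size_t p2 = p;
    while (p2 < ops.size() && ops[p2] == op) p2++;
    int len = (int) (p2 - p);
    cig += std::to_string(len); cig.push_back(op);
    if (op == 'M') {
      for (size_t u = p; u < p2; ++u) {
        if (mmflag[u]) {
          res.ev_type.push_back(1);
          res.ev_refpos.push_back(rp + (int) (u - p));
          res.ev_qpos.push_back(qp + (int) (u - p));
          res.ev_len.push_back(1);
          res.ev_alt.push_back(std::string(1, (char) toupper((unsigned char) q[qp + (u - p)])));
        }
      }
      qp += len; rp += len;
    } else if (op == 'I') {
      res.ev_type.push_back(2);
      res.ev_refpos.push_back(rp);
      res.ev_qpos.push_back(qp);
      res.ev_len.push_back(len);
      res.ev_alt.push_back(upper_seq(q.substr(qp, len)));
      qp += len;
    } else { // D
      res.ev_type.push_back(3);
      res.ev_refpos.push_back(rp);
      res.ev_qpos.push_back(qp);
      res.ev_len.push_back(len);
      res.ev_alt.push_back("");
      rp += len;
    }
    p = p2;
  }
  res.cigar = cig;
  res.aln_ref_len = rp - jstart;
  return res;
}

// Count matches of q laid on ref sequence at diagonal d (no gaps).
static int diag_matches(const std::string& q, const std::string& ref, int d) {
  int m = (int) q.size();
  int n = (int) ref.size();
  int cnt = 0;
  for (int i = 0; i < m; ++i) {
    int j = d + i;
    if (j < 0 || j >= n) continue;
    if (toupper((unsigned char) q[i]) == toupper((unsigned char) ref[j]) && base_code(q[i]) >= 0) cnt++;
  }
  return cnt;
}

// ---------------------------------------------------------------------------
// Read mapping: glocal alignment of whole reads with candidate enumeration
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_map_reads(SEXP xp, CharacterVector reads, double min_identity,
                   double margin_frac, int band, double gap_open, double gap_ext,
                   int seed_step, int max_candidates, int max_per_kmer) {
  XPtr<KmerIndex> idx(xp);
  int nr = reads.size();
  IntegerVector out_status(nr);     // 0 accept, 1 NO_HIT, 2 MULTI_LOCUS
  IntegerVector out_chrom(nr, NA_INTEGER);
  IntegerVector out_start(nr, NA_INTEGER);
  CharacterVector out_strand(nr, NA_STRING);
  NumericVector out_identity(nr, NA_REAL);
  NumericVector out_best(nr, NA_REAL);
  NumericVector out_second(nr, NA_REAL);
  IntegerVector out_nloci(nr, NA_INTEGER);
  IntegerVector out_reflen(nr, NA_INTEGER);
  CharacterVector out_cigar(nr, NA_STRING);
  std::vector<int> ev_read, ev_type, ev_refpos, ev_qpos, ev_len;
  std::vector<std::string> ev_alt;

  for (int r = 0; r < nr; ++r) {
    std::string fwd = upper_seq(as<std::string>(reads[r]));
    int m = (int) fwd.size();
    if (m < idx->k) { out_status[r] = 1; continue; }
    std::string rev = revcomp(fwd);
    std::unordered_map<uint64_t, SeedBucket> buckets;
    collect_buckets(*idx, fwd, 0, seed_step, max_per_kmer, buckets);
    collect_buckets(*idx, rev, 1, seed_step, max_per_kmer, buckets);
    if (buckets.empty()) { out_status[r] = 1; continue; }
    std::vector<SeedBucket> cand;
    cand.reserve(buckets.size());
    for (auto& kv : buckets) cand.push_back(kv.second);
    std::sort(cand.begin(), cand.end(), [](const SeedBucket& a, const SeedBucket& b) {
      return a.count > b.count;
    });
    if ((int) cand.size() > max_candidates) cand.resize(max_candidates);
    // score candidates by gapless diagonal matches first
    struct Scored { int seqid; int diag; int strand; double score; };
    std::vector<Scored> scored;
    for (auto& c : cand) {
      const std::string& q = c.strand == 0 ? fwd : rev;
      const std::string& ref = idx->seqs[c.seqid];
      int sc = diag_matches(q, ref, c.diag);
      scored.push_back({c.seqid, c.diag, c.strand, (double) sc});
    }
    // deduplicate candidates pointing at the same locus
    std::sort(scored.begin(), scored.end(), [](const Scored& a, const Scored& b) {
      return a.score > b.score;
    });
    std::vector<Scored> uniq;
    for (auto& s : scored) {
      bool dup = false;
      for (auto& u : uniq) {
        if (u.seqid == s.seqid && u.strand == s.strand && std::abs(u.diag - s.diag) <= 2 * band + 4) {
          dup = true; break;
        }
      }
      if (!dup) uniq.push_back(s);
    }
    Scored best = uniq[0];
    double best_score = best.score;
    double identity = best_score / (double) m;
    AlnResult aln;
    bool need_dp = identity < min_identity;
    const std::string& bref = idx->seqs[best.seqid];
    const std::string& bq = best.strand == 0 ? fwd : rev;
    int ws = 0, refstart = 0;
    if (need_dp) {
      // banded DP around best candidate diagonal
      ws = std::max(0, best.diag - band);
      int we = std::min((int) bref.size(), best.diag + m + band);
      if (we > ws) {
        std::string win = bref.substr(ws, we - ws);
        aln = banded_fit(bq, win, best.diag - ws, band, gap_open, gap_ext);
        if (aln.ok) {
          best_score = (double) aln.matches;
          identity = best_score / (double) m;
        }
      }
    }
    double second = NEG_INF;
    int nloci = 1;
    int refined = 0;
    double margin = margin_frac * m;
    for (size_t u = 1; u < uniq.size(); ++u) {
      double s2 = uniq[u].score;
      // refine near-best competitors with DP when gapless underestimates
      // (capped: refinement only matters near the margin boundary)
      if (refined < 2 &&
          s2 < best_score - margin && s2 / (double) m >= min_identity - 0.15) {
        refined++;
        const std::string& ref2 = idx->seqs[uniq[u].seqid];
        const std::string& q2 = uniq[u].strand == 0 ? fwd : rev;
        int ws2 = std::max(0, uniq[u].diag - band);
        int we2 = std::min((int) ref2.size(), uniq[u].diag + m + band);
        if (we2 > ws2) {
          AlnResult a2 = banded_fit(q2, ref2.substr(ws2, we2 - ws2), uniq[u].diag - ws2,
                                    band, gap_open, gap_ext);
          if (a2.ok) s2 = std::max(s2, (double) a2.matches);
        }
      }
      if (s2 > second) second = s2;
      if (s2 >= best_score - margin) nloci++;
    }
    out_best[r] = best_score;
    // a "second hit" is only reported when the competitor could plausibly
    // align (near the acceptance floor); random-diagonal background matches
    // are not competing loci and must not depress the uniqueness score
    bool real_second = second > NEG_INF / 2 &&
      second >= (min_identity - 0.15) * (double) m;
    out_second[r] = real_second ? second : NA_REAL;
    out_identity[r] = identity;
    out_nloci[r] = nloci;
    if (identity < min_identity) { out_status[r] = 1; continue; }
    if (second > NEG_INF / 2 && second >= best_score - margin) { out_status[r] = 2; continue; }
    // accepted: emit record
    if (need_dp && aln.ok) {
      refstart = ws + aln.ref_start;
      out_cigar[r] = aln.cigar;
      out_reflen[r] = aln.aln_ref_len;
      for (size_t e = 0; e < aln.ev_type.size(); ++e) {
        ev_read.push_back(r + 1);
        ev_type.push_back(aln.ev_type[e]);
        ev_refpos.push_back(ws + aln.ev_refpos[e]);
        ev_qpos.push_back(aln.ev_qpos[e]);
        ev_len.push_back(aln.ev_len[e]);
        ev_alt.push_back(aln.ev_alt[e]);
      }
    } else {
      // gapless placement; clamp to reference bounds
      int st = best.diag;
      if (st < 0 || st + m > (int) bref.size()) { out_status[r] = 1; continue; }
      refstart = st;
      out_cigar[r] = std::to_string(m) + "M";
      out_reflen[r] = m;
      for (int i = 0; i < m; ++i) {
        if (toupper((unsigned char) bq[i]) != toupper((unsigned char) bref[st + i]) ||
            base_code(bq[i]) < 0) {
          ev_read.push_back(r + 1);
          ev_type.push_back(1);
          ev_refpos.push_back(st + i);
          ev_qpos.push_back(i);
          ev_len.push_back(1);
          ev_alt.push_back(std::string(1, bq[i]));
        }
      }
    }
    out_status[r] = 0;
    out_chrom[r] = best.seqid + 1;
    out_start[r] = refstart;
    out_strand[r] = best.strand == 0 ? "+" : "-";
  }
  return List::create(
    _["status"] = out_status, _["chrom"] = out_chrom, _["start"] = out_start,
    _["strand"] = out_strand, _["identity"] = out_identity, _["best"] = out_best,
    _["second"] = out_second, _["n_loci"] = out_nloci, _["ref_span"] = out_reflen,
    _["cigar"] = out_cigar,
    _["events"] = List::create(
      _["read"] = wrap(ev_read), _["type"] = wrap(ev_type),
      _["refpos"] = wrap(ev_refpos), _["qpos"] = wrap(ev_qpos),
      _["len"] = wrap(ev_len), _["alt"] = wrap(ev_alt)));
}

// ---------------------------------------------------------------------------
// Banded local alignment (Smith-Waterman) for repeat masking / LTR harvest
// ---------------------------------------------------------------------------

struct LocalHit {
  int qstart, qend, tstart, tend, matches, alnlen, strand, target;
  double score;
};

static bool banded_local(const std::string& q, const std::string& w, int doff,
                         int band, double gap_open, double gap_ext, LocalHit& hit) {
  int m = (int) q.size();
  int n = (int) w.size();
  if (m == 0 || n == 0) return false;
  int W = 2 * band + 1;
  std::vector<double> H((m + 1) * W, 0.0), E((m + 1) * W, NEG_INF), F((m + 1) * W, NEG_INF);
  std::vector<uint8_t> TH((m + 1) * W, 3), TE((m + 1) * W, 0), TF((m + 1) * W, 0);
  auto centre = [&](int i) { return i + doff; };
  double bestScore = 0.0; int bi = -1, bt = -1;
  for (int i = 1; i <= m; ++i) {
    int ci = centre(i);
    char qc = q[i - 1];
    for (int t = 0; t < W; ++t) {
      int j = ci + t - band;
      size_t cell = (size_t) i * W + t;
      H[cell] = 0.0; TH[cell] = 3; E[cell] = F[cell] = NEG_INF;
      if (j < 1 || j > n) continue;
      if (t - 1 >= 0) {
        double openE = H[(size_t) i * W + (t - 1)] - gap_open - gap_ext;
        double extE  = E[(size_t) i * W + (t - 1)] - gap_ext;
        if (openE >= extE) { E[cell] = openE; TE[cell] = 0; } else { E[cell] = extE; TE[cell] = 1; }
      }
      if (t + 1 < W) {
        double openF = H[(size_t) (i - 1) * W + (t + 1)] - gap_open - gap_ext;
        double extF  = F[(size_t) (i - 1) * W + (t + 1)] - gap_ext;
        if (openF >= extF) { F[cell] = openF; TF[cell] = 0; } else { F[cell] = extF; TF[cell] = 1; }
      }
      double sc = (toupper((unsigned char) qc) == toupper((unsigned char) w[j - 1]) &&
                   base_code(qc) >= 0) ? 1.0 : -1.0;
      double diag = H[(size_t) (i - 1) * W + t] + sc;
      double best = 0.0; uint8_t tb = 3;
      if (diag > best) { best = diag; tb = 0; }
      if (E[cell] > best) { best = E[cell]; tb = 1; }
      if (F[cell] > best) { best = F[cell]; tb = 2; }
      H[cell] = best; TH[cell] = tb;
      if (best > bestScore) { bestScore = best; bi = i; bt = t; }
    }
  }
  if (bi < 0 || bestScore <= 0) return false;
  // traceback
  int i = bi, t = bt, state = 0;
  int matches = 0, alnlen = 0;
  while (true) {
    size_t cell = (size_t) i * W + t;
    if (state == 0) {
      uint8_t tb = TH[cell];
      if (tb == 3) break;
      if (tb == 0) {
        int j = centre(i) + t - band;
        if (toupper((unsigned char) q[i - 1]) == toupper((unsigned char) w[j - 1]) &&
            base_code(q[i - 1]) >= 0) matches++;
        alnlen++;
        i -= 1;
      } else state = (tb == 1) ? 1 : 2;
    } else if (state == 1) {
      alnlen++; t -= 1; state = TE[cell] == 0 ? 0 : 1;
    } else {
      alnlen++; i -= 1; t += 1; state = TF[cell] == 0 ? 0 : 2;
    }
    if (i <= 0) break;
  }
  int jend = centre(bi) + bt - band;
  int jstart = centre(i) + t - band;
  hit.qstart = i; hit.qend = bi;
  hit.tstart = jstart; hit.tend = jend;
  hit.matches = matches; hit.alnlen = alnlen;
  hit.score = bestScore;
  return true;
}

// [[Rcpp::export]]
List cpp_local_hits(CharacterVector queries, SEXP xp, double min_identity,
                    int min_len, int band, double gap_open, double gap_ext,
                    int seed_step, int max_targets, int max_per_kmer,
                    int stop_unexplained) {
  XPtr<KmerIndex> idx(xp);
  std::vector<int> o_query, o_qstart, o_qend, o_target, o_tstart, o_tend, o_strand;
  std::vector<double> o_identity;
  int nq = queries.size();
  for (int r = 0; r < nq; ++r) {
    std::string fwd = upper_seq(as<std::string>(queries[r]));
    int m = (int) fwd.size();
    if (m < idx->k) continue;
    std::string rev = revcomp(fwd);
    std::unordered_map<uint64_t, SeedBucket> buckets;
    collect_buckets(*idx, fwd, 0, seed_step, max_per_kmer, buckets);
    collect_buckets(*idx, rev, 1, seed_step, max_per_kmer, buckets);
    if (buckets.empty()) continue;
    std::vector<SeedBucket> cand;
    for (auto& kv : buckets) cand.push_back(kv.second);
    std::sort(cand.begin(), cand.end(), [](const SeedBucket& a, const SeedBucket& b) {
      return a.count > b.count;
    });
    // best bucket per (target, strand, distinct diagonal region)
    std::vector<SeedBucket> picked;
    for (auto& c : cand) {
      bool dup = false;
      for (auto& p : picked) {
        if (p.seqid == c.seqid && p.strand == c.strand && std::abs(p.diag - c.diag) <= 2 * band + 8) {
          dup = true; break;
        }
      }
      if (!dup) picked.push_back(c);
      if ((int) picked.size() >= max_targets) break;
    }
    std::vector<bool> covered(m, false);
    int n_covered = 0;
    for (auto& c : picked) {
      const std::string& q = c.strand == 0 ? fwd : rev;
      const std::string& tg = idx->seqs[c.seqid];
      int ws = std::max(0, c.diag - band);
      int we = std::min((int) tg.size(), c.diag + m + band);
      if (we <= ws) continue;
      LocalHit hit;
      if (!banded_local(q, tg.substr(ws, we - ws), c.diag - ws, band, gap_open, gap_ext, hit))
        continue;
      if (hit.qend - hit.qstart < min_len) continue;
      double ident = (double) hit.matches / (double) hit.alnlen;
      if (ident < min_identity) continue;
      // map interval to forward-read coordinates
      int fs, fe;
      if (c.strand == 0) { fs = hit.qstart; fe = hit.qend; }
      else { fs = m - hit.qend; fe = m - hit.qstart; }
      o_query.push_back(r + 1);
      o_qstart.push_back(fs); o_qend.push_back(fe);
      o_target.push_back(c.seqid + 1);
      o_tstart.push_back(ws + hit.tstart); o_tend.push_back(ws + hit.tend);
      o_strand.push_back(c.strand == 0 ? 1 : -1);
      o_identity.push_back(ident);
      for (int p = fs; p < fe; ++p) if (!covered[p]) { covered[p] = true; n_covered++; }
      if (stop_unexplained > 0 && m - n_covered < stop_unexplained) break;
    }
  }
  return List::create(
    _["query"] = wrap(o_query), _["qstart"] = wrap(o_qstart), _["qend"] = wrap(o_qend),
    _["target"] = wrap(o_target), _["tstart"] = wrap(o_tstart), _["tend"] = wrap(o_tend),
    _["strand"] = wrap(o_strand), _["identity"] = wrap(o_identity));
}

// ---------------------------------------------------------------------------
// 454-style error model: linear quality decay, phred-scaled substitutions,
// homopolymer run-length errors.  Uses R's RNG stream.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_apply_454(CharacterVector seqs, double q_start, double q_end,
                   double subst_scale, double homopoly_rate) {
  int n = seqs.size();
  CharacterVector out_seq(n), out_qual(n);
  const char* bases = "ACGT";
  for (int r = 0; r < n; ++r) {
    std::string s = upper_seq(as<std::string>(seqs[r]));
    // homopolymer run errors on the template: runs >= 3 gain/lose one base
    std::string t;
    t.reserve(s.size() + 8);
    size_t i = 0;
    while (i < s.size()) {
      size_t j = i;
      while (j < s.size() && s[j] == s[i]) j++;
      size_t runlen = j - i;
      size_t outlen = runlen;
      if (runlen >= 3 && homopoly_rate > 0 && R::unif_rand() < homopoly_rate) {
        outlen = (R::unif_rand() < 0.5) ? runlen - 1 : runlen + 1;
      }
      t.append(outlen, s[i]);
      i = j;
    }
    int m = (int) t.size();
    std::string qual(m, 'I');
    for (int p = 0; p < m; ++p) {
      double frac = m > 1 ? (double) p / (double) (m - 1) : 0.0;
      double qv = q_start + (q_end - q_start) * frac;
      if (qv < 2) qv = 2;
      if (qv > 41) qv = 41;
      double perr = subst_scale * std::pow(10.0, -qv / 10.0);
      if (perr > 0 && R::unif_rand() < perr) {
        char cur = t[p];
        char nb = cur;
        while (nb == cur) nb = bases[(int) std::floor(R::unif_rand() * 4.0)];
        t[p] = nb;
      }
      qual[p] = (char) (33 + (int) std::lround(qv));
    }
    out_seq[r] = t;
    out_qual[r] = qual;
  }
  return List::create(_["seq"] = out_seq, _["qual"] = out_qual);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) out[i] = revcomp(upper_seq(as<std::string>(seqs[i])));
  return out;
}
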