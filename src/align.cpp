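// Seed-and-extend ungapped search, pileup accumulation and greedy sequence
// clustering. Everything here is deterministic: candidate loci are visited in
// sorted order and ties are broken by (chromosome, start, strand).
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int baseCode(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char rcBase(char c) {
  switch (c) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default: return 'N';
  }
}

static std::string revComp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::size_type i = 0; i < r.size(); ++i) r[i] = rcBase(r[i]);
  return r;
}

// 2-bit packed k-mer over [start, start+k); returns false on non-ACGT.
static inline bool packKmer(const std::string& s, size_t start, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = baseCode(s[start + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

struct GenomeIndex {
  std::string seq;                 // concatenated chromosomes
  std::vector<size_t> cum;         // cum[i] = global start of chrom i; cum[n] = total
  int k;
  std::vector<std::pair<uint64_t, uint32_t> > kp; // sorted (kmer, global pos)

  int chromOf(size_t gpos) const {
    // index of chromosome containing gpos
    int lo = 0, hi = (int)cum.size() - 2;
    while (lo < hi) {
      int mid = (lo + hi + 1) / 2;
      if (cum[mid] <= gpos) lo = mid; else hi = mid - 1;
    }
    return lo;
  }
};

static void buildIndex(const CharacterVector& refs, int k, GenomeIndex& gi) {
  gi.k = k;
  gi.cum.clear();
  gi.seq.clear();
  size_t total = 0;
  for (int i = 0; i < refs.size(); ++i) {
    gi.cum.push_back(total);
    std::string s = as<std::string>(refs[i]);
    total += s.size();
    gi.seq += s;
  }
  gi.cum.push_back(total);
  gi.kp.clear();
  gi.kp.reserve(total);
  for (int c = 0; c < refs.size(); ++c) {
    size_t beg = gi.cum[c], end = gi.cum[c + 1];
    if (end - beg < (size_t)k) continue;
    for (size_t p = beg; p + k <= end; ++p) {
      uint64_t key;
      if (packKmer(gi.seq, p, k, key)) gi.kp.push_back(std::make_pair(key, (uint32_t)p));
    }
  }
  std::sort(gi.kp.begin(), gi.kp.end());
}

// mismatches of query placed at global pos; early exit above cap
static inline int countMismatches(const GenomeIndex& gi, const std::string& q,
                                  size_t gpos, int cap) {
  int mm = 0;
  for (size_t i = 0; i < q.size(); ++i) {
    if (gi.seq[gpos + i] != q[i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct Hit { int chrom; int start; int strand; int mm; }; // start 1-based local

static void collectCandidates(const GenomeIndex& gi, const std::string& q,
                              int seedStep, std::vector<size_t>& cands) {
  int k = gi.k;
  int len = (int)q.size();
  if (len < k) return;
  std::vector<int> offs;
  for (int o = 0; o + k <= len; o += seedStep) offs.push_back(o);
  if (offs.empty() || offs.back() != len - k) offs.push_back(len - k);
  for (size_t oi = 0; oi < offs.size(); ++oi) {
    int o = offs[oi];
    uint64_t key;
    if (!packKmer(q, o, k, key)) continue;
    std::pair<uint64_t, uint32_t> lo(key, 0u);
    std::pair<uint64_t, uint32_t> hi(key, 0xffffffffu);
    std::vector<std::pair<uint64_t, uint32_t> >::const_iterator it =
      std::lower_bound(gi.kp.begin(), gi.kp.end(), lo);
    std::vector<std::pair<uint64_t, uint32_t> >::const_iterator en =
      std::upper_bound(gi.kp.begin(), gi.kp.end(), hi);
    for (; it != en; ++it) {
      int64_t start = (int64_t)it->second - o;
      if (start < 0) continue;
      size_t s = (size_t)start;
      int c = gi.chromOf(it->second);
      if (s < gi.cum[c] || s + len > gi.cum[c + 1]) continue;
      cands.push_back(s);
    }
  }
  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
}

// Align reads to a set of reference sequences.
// reads: character vector; maxMm: per-read mismatch cap; seedStep: offset
// between successive exact seeds; reportAll: emit every locus within the
// mismatch cap (probe mapping) instead of best-only with tie counting.
// Returned starts are 1-based, chrom is a 1-based index into refs.
// [[Rcpp::export]]
DataFrame cpp_align(CharacterVector refs, CharacterVector reads,
                    IntegerVector maxMm, int k, int seedStep, bool reportAll) {
  GenomeIndex gi;
  buildIndex(refs, k, gi);

  std::vector<int> outRead, outChrom, outStart, outStrand, outMm, outNbest;

  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    if ((int)fwd.size() < k) continue;
    std::string rev = revComp(fwd);
    int cap = maxMm[r % maxMm.size()];
    std::vector<Hit> hits;
    int best = cap + 1;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = (strand == 0) ? fwd : rev;
      std::vector<size_t> cands;
      collectCandidates(gi, q, seedStep, cands);
      for (size_t ci = 0; ci < cands.size(); ++ci) {
        size_t s = cands[ci];
        int mm = countMismatches(gi, q, s, cap);
        if (mm > cap) continue;
        int c = gi.chromOf(s);
        Hit h;
        h.chrom = c + 1;
        h.start = (int)(s - gi.cum[c]) + 1;
        h.strand = strand;
        h.mm = mm;
        if (reportAll) {
          hits.push_back(h);
        } else {
          if (mm < best) { best = mm; hits.clear(); hits.push_back(h); }
          else if (mm == best) hits.push_back(h);
        }
      }
    }
    if (hits.empty()) continue;
    if (reportAll) {
      for (size_t i = 0; i < hits.size(); ++i) {
        outRead.push_back(r + 1); outChrom.push_back(hits[i].chrom);
        outStart.push_back(hits[i].start); outStrand.push_back(hits[i].strand);
        outMm.push_back(hits[i].mm); outNbest.push_back((int)hits.size());
      }
    } else {
      // deterministic representative: lowest (chrom, start, strand)
      size_t bi = 0;
      for (size_t i = 1; i < hits.size(); ++i) {
        if (hits[i].chrom < hits[bi].chrom ||
            (hits[i].chrom == hits[bi].chrom &&
             (hits[i].start < hits[bi].start ||
              (hits[i].start == hits[bi].start && hits[i].strand < hits[bi].strand))))
          bi = i;
      }
      outRead.push_back(r + 1); outChrom.push_back(hits[bi].chrom);
      outStart.push_back(hits[bi].start); outStrand.push_back(hits[bi].strand);
      outMm.push_back(hits[bi].mm); outNbest.push_back((int)hits.size());
    }
  }

  return DataFrame::create(
    _["read"] = outRead, _["chrom"] = outChrom, _["start"] = outStart,
    _["strand"] = outStrand, _["mismatches"] = outMm,
    _["n_equal_best"] = outNbest);
}

// Per-base pileup. seq must already be reference-oriented. chrom is a 1-based
// index into refs, start 1-based. Returns counts for covered positions only.
// [[Rcpp::export]]
DataFrame cpp_pileup(CharacterVector refs, IntegerVector chrom,
                     IntegerVector start, CharacterVector seq) {
  int nref = refs.size();
  std::vector<int> outChrom, outPos;
  std::vector<int> outA, outC, outG, outT;

  // group alignment rows by chromosome to bound memory at one chrom's counts
  std::vector<std::vector<int> > byChrom(nref);
  for (int i = 0; i < chrom.size(); ++i) {
    int c = chrom[i] - 1;
    if (c < 0 || c >= nref) stop("chromosome index out of range");
    byChrom[c].push_back(i);
  }

  for (int c = 0; c < nref; ++c) {
    if (byChrom[c].empty()) continue;
    std::string ref = as<std::string>(refs[c]);
    size_t L = ref.size();
    std::vector<uint32_t> cnt(4 * L, 0u);
    for (size_t j = 0; j < byChrom[c].size(); ++j) {
      int i = byChrom[c][j];
      std::string s = as<std::string>(seq[i]);
      size_t s0 = (size_t)(start[i] - 1);
      if (s0 + s.size() > L) stop("alignment outside chromosome");
      for (size_t p = 0; p < s.size(); ++p) {
        int b = baseCode(s[p]);
        if (b >= 0) cnt[4 * (s0 + p) + b]++;
      }
    }
    for (size_t p = 0; p < L; ++p) {
      uint32_t a = cnt[4 * p], cc = cnt[4 * p + 1], g = cnt[4 * p + 2], t = cnt[4 * p + 3];
      if (a + cc + g + t == 0) continue;
      outChrom.push_back(c + 1); outPos.push_back((int)p + 1);
      outA.push_back((int)a); outC.push_back((int)cc);
      outG.push_back((int)g); outT.push_back((int)t);
    }
  }
  return DataFrame::create(_["chrom"] = outChrom, _["pos"] = outPos,
                           _["A"] = outA, _["C"] = outC,
                           _["G"] = outG, _["T"] = outT);
}

// For each alignment, emit the base it carries at each queried site it
// overlaps. Sites must be sorted by (chrom, pos). Bases returned as codes
// 0..3 (ACGT), -1 for ambiguous.
// [[Rcpp::export]]
DataFrame cpp_read_bases(IntegerVector chrom, IntegerVector start,
                         CharacterVector seq, IntegerVector siteChrom,
                         IntegerVector sitePos) {
  int ns = siteChrom.size();
  std::vector<int> outAln, outSite, outBase;
  // per-chrom sorted site position vectors with original indices
  std::unordered_map<int, std::vector<std::pair<int, int> > > sites;
  for (int i = 0; i < ns; ++i)
    sites[siteChrom[i]].push_back(std::make_pair(sitePos[i], i));
  for (std::unordered_map<int, std::vector<std::pair<int, int> > >::iterator it = sites.begin();
       it != sites.end(); ++it)
    std::sort(it->second.begin(), it->second.end());

  for (int i = 0; i < chrom.size(); ++i) {
    std::unordered_map<int, std::vector<std::pair<int, int> > >::iterator f =
      sites.find(chrom[i]);
    if (f == sites.end()) continue;
    std::string s = as<std::string>(seq[i]);
    int a0 = start[i], a1 = start[i] + (int)s.size() - 1;
    std::vector<std::pair<int, int> >& v = f->second;
    std::vector<std::pair<int, int> >::iterator lo =
      std::lower_bound(v.begin(), v.end(), std::make_pair(a0, -1));
    for (; lo != v.end() && lo->first <= a1; ++lo) {
      outAln.push_back(i + 1);
      outSite.push_back(lo->second + 1);
      outBase.push_back(baseCode(s[lo->first - a0]));
    }
  }
  return DataFrame::create(_["aln"] = outAln, _["site"] = outSite,
                           _["base"] = outBase);
}

// Greedy clustering of sequences (CD-HIT-EST-like contract): a sequence joins
// the first representative it matches at >= identity over an ungapped overlap
// covering >= coverage of both sequences, on either strand; otherwise it
// founds a new cluster. Input order defines greediness (caller pre-sorts).
// Returns 1-based representative index per sequence.
// [[Rcpp::export]]
IntegerVector cpp_greedy_cluster(CharacterVector seqs, double identity,
                                 double coverage, int word) {
  int n = seqs.size();
  IntegerVector rep(n);
  std::vector<std::string> fwd(n);
  for (int i = 0; i < n; ++i) fwd[i] = as<std::string>(seqs[i]);
  std::vector<int> reps;
  // word-mer -> representative ids containing it (on forward strand)
  std::unordered_map<uint64_t, std::vector<int> > wordMap;

  for (int i = 0; i < n; ++i) {
    const std::string& q = fwd[i];
    std::string qr = revComp(q);
    int assigned = -1;
    // candidate representatives sharing a word with q on either strand
    std::vector<int> cand;
    for (int strand = 0; strand < 2 && assigned < 0; ++strand) {
      const std::string& s = (strand == 0) ? q : qr;
      if ((int)s.size() < word) continue;
      for (size_t o = 0; o + word <= s.size(); ++o) {
        uint64_t key;
        if (!packKmer(s, o, word, key)) continue;
        std::unordered_map<uint64_t, std::vector<int> >::iterator it = wordMap.find(key);
        if (it != wordMap.end())
          cand.insert(cand.end(), it->second.begin(), it->second.end());
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

    for (size_t ci = 0; ci < cand.size() && assigned < 0; ++ci) {
      const std::string& t = fwd[cand[ci]];
      int lq = (int)q.size(), lt = (int)t.size();
      int minOv = (int)std::ceil(coverage * (double)std::max(lq, lt));
      for (int strand = 0; strand < 2 && assigned < 0; ++strand) {
        const std::string& s = (strand == 0) ? q : qr;
        // ungapped offsets: s starts at position d of t (d may be negative)
        for (int d = -(lq - minOv); d <= lt - minOv; ++d) {
          int b0 = std::max(0, d), b1 = std::min(lt, d + lq); // overlap in t coords
          int ov = b1 - b0;
          if (ov < minOv) continue;
          int match = 0;
          for (int p = b0; p < b1; ++p)
            if (t[p] == s[p - d]) match++;
          if ((double)match / (double)ov >= identity) { assigned = cand[ci]; break; }
        }
      }
    }
    if (assigned < 0) {
      rep[i] = i + 1;
      reps.push_back(i);
      if ((int)q.size() >= word) {
        for (size_t o = 0; o + word <= q.size(); ++o) {
          uint64_t key;
          if (packKmer(q, o, word, key)) wordMap[key].push_back(i);
        }
      }
    } else {
      rep[i] = assigned + 1;
    }
  }
  return rep;
}

// In-silico restriction digest cut positions for a 5-base motif with one
// ambiguous (W = A/T) middle position, e.g. ApeKI GCWGC. Returns 1-based
// positions of the first motif base.
// [[Rcpp::export]]
IntegerVector cpp_motif_positions(CharacterVector seq, CharacterVector motif) {
  std::string s = as<std::string>(seq[0]);
  std::string m = as<std::string>(motif[0]);
  std::vector<int> out;
  if (s.size() < m.size()) return wrap(out);
  for (size_t p = 0; p + m.size() <= s.size(); ++p) {
    bool ok = true;
    for (size_t j = 0; j < m.size(); ++j) {
      char mc = m[j], sc = s[p + j];
      if (mc == 'W') { if (sc != 'A' && sc != 'T') { ok = false; break; } }
      else if (mc != sc) { ok = false; break; }
    }
    if (ok) out.push_back((int)p + 1);
  }
  return wrap(out);
}
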