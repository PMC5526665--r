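// Seed-and-extend nucleotide local alignment.
//
// Exact k-mer seeds shared between query and subject are clustered by
// diagonal, each cluster is resolved with a banded affine-gap local
// (Smith-Waterman) DP restricted to a window around the seeds, and
// overlapping alignments are deduplicated keeping the highest score.
// Any base outside {A,C,G,T} (case-insensitive) never matches, so N acts
// as a universal mismatch.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_char(c);
  return r;
}

// enumerate valid (ACGT-only) k-mers as 2-bit codes with their start position
static void enumerate_kmers(const std::string& s, int k,
                            std::vector<std::pair<uint64_t, int> >& out) {
  const int n = (int)s.size();
  if (n < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;  // length of current valid run
  for (int i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) out.push_back(std::make_pair(code, i - k + 1));
  }
}

struct Seed { int q, s, d; };  // d = s - q

struct Aln {
  int score, q0, q1, s0, s1, ident, cols;
  int strand;  // +1 / -1
};

// Banded affine local alignment over windows q[q0,q1) x s[s0,s1), with the
// window diagonal (sj - s0) - (qi - q0) restricted to [dlo, dhi].
// Returns best local alignment in window coordinates (half-open), or
// score<=0 when the window contains nothing positive.
static Aln banded_sw(const std::string& q, const std::string& s,
                     int q0, int q1, int s0, int s1, int dlo, int dhi,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int NEG = -(1 << 28);
  const int m = q1 - q0, n = s1 - s0;
  const int w = dhi - dlo + 1;
  Aln best; best.score = 0; best.q0 = best.q1 = best.s0 = best.s1 = 0;
  best.ident = 0; best.cols = 0; best.strand = 1;
  if (m <= 0 || n <= 0 || w <= 0) return best;

  // H/E/F stored as full (m+1) x w matrices; w is the band width (small).
  std::vector<int> H((size_t)(m + 1) * w, 0), E((size_t)(m + 1) * w, NEG),
      F((size_t)(m + 1) * w, NEG);
  auto idx = [w](int i, int off) { return (size_t)i * w + off; };

  int bi = 0, boff = 0, bscore = 0;
  for (int i = 0; i <= m; ++i) {
    for (int off = 0; off < w; ++off) {
      int j = i + dlo + off;  // subject window coordinate
      if (j < 0 || j > n) { H[idx(i, off)] = (i == 0 || j <= 0) ? 0 : NEG; continue; }
      if (i == 0 || j == 0) { H[idx(i, off)] = 0; E[idx(i, off)] = NEG; F[idx(i, off)] = NEG; continue; }
      // E: gap in query (consume subject) -> from (i, j-1) = off-1
      int e = NEG;
      if (off - 1 >= 0) {
        int hprev = H[idx(i, off - 1)], eprev = E[idx(i, off - 1)];
        if (hprev > NEG / 2) e = hprev + gap_open + gap_extend;
        if (eprev > NEG / 2 && eprev + gap_extend > e) e = eprev + gap_extend;
      }
      // F: gap in subject (consume query) -> from (i-1, j) = off+1
      int f = NEG;
      if (off + 1 < w) {
        int hup = H[idx(i - 1, off + 1)], fup = F[idx(i - 1, off + 1)];
        if (hup > NEG / 2) f = hup + gap_open + gap_extend;
        if (fup > NEG / 2 && fup + gap_extend > f) f = fup + gap_extend;
      }
      // diagonal from (i-1, j-1) = same off
      int a = base_code(q[q0 + i - 1]), b = base_code(s[s0 + j - 1]);
      int sub = (a >= 0 && a == b) ? match : mismatch;
      int diag = H[idx(i - 1, off)];
      int h = 0;
      if (diag > NEG / 2 && diag + sub > h) h = diag + sub;
      if (e > h) h = e;
      if (f > h) h = f;
      H[idx(i, off)] = h;
      E[idx(i, off)] = e;
      F[idx(i, off)] = f;
      if (h > bscore) { bscore = h; bi = i; boff = off; }
    }
  }
  if (bscore <= 0) return best;

  // traceback from the best cell until H hits 0
  int i = bi, off = boff, state = 0;  // 0=H, 1=E, 2=F
  int qe = bi, se = bi + dlo + boff;
  int ident = 0, cols = 0;
  while (true) {
    int j = i + dlo + off;
    if (state == 0) {
      int h = H[idx(i, off)];
      if (h == 0) break;
      int e = E[idx(i, off)];
      int a = base_code(q[q0 + i - 1]), b = base_code(s[s0 + j - 1]);
      int sub = (a >= 0 && a == b) ? match : mismatch;
      int diag = (i >= 1 && j >= 1) ? H[idx(i - 1, off)] : NEG;
      if (diag > NEG / 2 && h == diag + sub) {
        ++cols; if (a >= 0 && a == b) ++ident;
        --i;  // off unchanged on the diagonal
      } else if (h == e) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {  // gap in query, consumed s[j-1]
      ++cols;
      int e = E[idx(i, off)];
      int hprev = (off - 1 >= 0) ? H[idx(i, off - 1)] : NEG;
      bool open = (hprev > NEG / 2 && e == hprev + gap_open + gap_extend);
      off -= 1;
      state = open ? 0 : 1;
    } else {  // gap in subject, consumed q[i-1]
      ++cols;
      int f = F[idx(i, off)];
      int hup = (off + 1 < w) ? H[idx(i - 1, off + 1)] : NEG;
      bool open = (hup > NEG / 2 && f == hup + gap_open + gap_extend);
      --i; off += 1;
      state = open ? 0 : 2;
    }
  }
  best.score = bscore;
  best.q0 = i; best.q1 = qe;
  best.s0 = i + dlo + off; best.s1 = se;
  best.ident = ident; best.cols = cols;
  return best;
}

// one strand of the pairwise search: seeds -> clusters -> banded windows
static void align_one_strand(const std::string& q, const std::string& s,
                             int k, int match, int mismatch, int gap_open,
                             int gap_extend, int band, int margin,
                             int strand, std::vector<Aln>& out) {
  const int qn = (int)q.size(), sn = (int)s.size();
  if (qn < k || sn < k) return;

  // index the shorter sequence, scan the longer
  std::vector<std::pair<uint64_t, int> > qk, sk;
  enumerate_kmers(q, k, qk);
  enumerate_kmers(s, k, sk);
  std::unordered_map<uint64_t, std::vector<int> > index;
  const bool index_query = qk.size() <= sk.size();
  const std::vector<std::pair<uint64_t, int> >& iv = index_query ? qk : sk;
  const std::vector<std::pair<uint64_t, int> >& sv = index_query ? sk : qk;
  index.reserve(iv.size() * 2);
  for (size_t t = 0; t < iv.size(); ++t) index[iv[t].first].push_back(iv[t].second);

  const size_t occ_cap = 64;  // skip hyper-repetitive k-mers
  std::vector<Seed> seeds;
  for (size_t t = 0; t < sv.size(); ++t) {
    std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
        index.find(sv[t].first);
    if (it == index.end() || it->second.size() > occ_cap) continue;
    for (size_t u = 0; u < it->second.size(); ++u) {
      int qpos = index_query ? it->second[u] : sv[t].second;
      int spos = index_query ? sv[t].second : it->second[u];
      Seed sd; sd.q = qpos; sd.s = spos; sd.d = spos - qpos;
      seeds.push_back(sd);
    }
  }
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed& a, const Seed& b) {
    if (a.d != b.d) return a.d < b.d;
    return a.s < b.s;
  });

  // greedy clustering by diagonal proximity, then by along-diagonal gap
  const int cluster_gap = std::max(margin, 200);
  struct Cluster { int dlo, dhi, qlo, qhi, slo, shi; };
  std::vector<Cluster> clusters;
  for (size_t t = 0; t < seeds.size(); ++t) {
    const Seed& sd = seeds[t];
    bool merged = false;
    if (!clusters.empty()) {
      Cluster& c = clusters.back();
      if (sd.d - c.dhi <= band && sd.s - c.shi <= cluster_gap) {
        c.dhi = std::max(c.dhi, sd.d);
        c.qlo = std::min(c.qlo, sd.q); c.qhi = std::max(c.qhi, sd.q);
        c.slo = std::min(c.slo, sd.s); c.shi = std::max(c.shi, sd.s);
        merged = true;
      }
    }
    if (!merged) {
      Cluster c; c.dlo = c.dhi = sd.d;
      c.qlo = c.qhi = sd.q; c.slo = c.shi = sd.s;
      clusters.push_back(c);
    }
  }

  for (size_t t = 0; t < clusters.size(); ++t) {
    const Cluster& c = clusters[t];
    int q0 = std::max(0, c.qlo - margin);
    int q1 = std::min(qn, c.qhi + k + margin);
    int s0 = std::max(0, c.slo - margin);
    int s1 = std::min(sn, c.shi + k + margin);
    // window diagonal range covering the cluster plus band slack
    int dlo = (c.dlo - (s0 - q0)) - band;
    int dhi = (c.dhi - (s0 - q0)) + band;
    Aln a = banded_sw(q, s, q0, q1, s0, s1, dlo, dhi, match, mismatch,
                      gap_open, gap_extend);
    if (a.score <= 0 || a.cols == 0) continue;
    a.q0 += q0; a.q1 += q0; a.s0 += s0; a.s1 += s0;
    a.strand = strand;
    out.push_back(a);
  }
}

static bool overlaps(const Aln& a, const Aln& b) {
  bool qo = a.q0 < b.q1 && b.q0 < a.q1;
  bool so = a.s0 < b.s1 && b.s0 < a.s1;
  return qo && so;
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
DataFrame align_pair_cpp(std::string query, std::string subject, int k,
                         int match, int mismatch, int gap_open, int gap_extend,
                         int band, int margin, double min_identity,
                         int min_length, bool both_strands) {
  std::vector<Aln> raw;
  align_one_strand(query, subject, k, match, mismatch, gap_open, gap_extend,
                   band, margin, +1, raw);
  if (both_strands) {
    std::string rc = revcomp(subject);
    std::vector<Aln> mraw;
    align_one_strand(query, rc, k, match, mismatch, gap_open, gap_extend,
                     band, margin, -1, mraw);
    // map subject coordinates back to the forward strand
    const int sn = (int)subject.size();
    for (size_t t = 0; t < mraw.size(); ++t) {
      Aln a = mraw[t];
      int s0 = sn - a.s1, s1 = sn - a.s0;
      a.s0 = s0; a.s1 = s1;
      raw.push_back(a);
    }
  }

  // deduplicate overlapping alignments, keeping the highest-scoring;
  // deterministic order: score desc, then q0, s0 asc
  std::sort(raw.begin(), raw.end(), [](const Aln& a, const Aln& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.q0 != b.q0) return a.q0 < b.q0;
    if (a.s0 != b.s0) return a.s0 < b.s0;
    return a.strand > b.strand;
  });
  std::vector<Aln> kept;
  for (size_t t = 0; t < raw.size(); ++t) {
    const Aln& a = raw[t];
    double pid = a.cols > 0 ? 100.0 * a.ident / a.cols : 0.0;
    if (a.cols < min_length) continue;
    if (pid < min_identity) continue;
    bool dup = false;
    for (size_t u = 0; u < kept.size(); ++u)
      if (overlaps(a, kept[u])) { dup = true; break; }
    if (!dup) kept.push_back(a);
  }

  const int nres = (int)kept.size();
  NumericVector pct(nres);
  IntegerVector len(nres), nid(nres), q0(nres), q1(nres), s0(nres), s1(nres),
      score(nres);
  CharacterVector strand(nres);
  for (int t = 0; t < nres; ++t) {
    const Aln& a = kept[t];
    pct[t] = 100.0 * a.ident / a.cols;
    len[t] = a.cols; nid[t] = a.ident;
    q0[t] = a.q0; q1[t] = a.q1; s0[t] = a.s0; s1[t] = a.s1;
    score[t] = a.score;
    strand[t] = a.strand > 0 ? "+" : "-";
  }
  return DataFrame::create(
      _["pct_identity"] = pct, _["aln_length"] = len, _["n_ident"] = nid,
      _["q_start"] = q0, _["q_end"] = q1, _["s_start"] = s0, _["s_end"] = s1,
      _["strand"] = strand, _["score"] = score,
      _["stringsAsFactors"] = false);
}

// Candidate gene pairs sharing at least one exact k-mer on either strand.
// Returns a 2-column matrix of 1-based (query index, subject index) pairs.
// [[Rcpp::export(name = ".kmer_pairs_cpp")]]
IntegerMatrix kmer_pairs_cpp(CharacterVector queries, CharacterVector subjects,
                             int k) {
  const int nq = queries.size(), ns = subjects.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  std::vector<std::pair<uint64_t, int> > kms;
  for (int j = 0; j < ns; ++j) {
    std::string s = as<std::string>(subjects[j]);
    kms.clear();
    enumerate_kmers(s, k, kms);
    uint64_t last = ~0ULL; bool have_last = false;
    std::sort(kms.begin(), kms.end());
    for (size_t t = 0; t < kms.size(); ++t) {
      if (have_last && kms[t].first == last) continue;
      last = kms[t].first; have_last = true;
      std::vector<int>& v = index[last];
      if (v.empty() || v.back() != j) v.push_back(j);
    }
  }
  std::vector<int> qi, si;
  std::vector<char> seen(ns, 0);
  std::vector<int> touched;
  for (int i = 0; i < nq; ++i) {
    std::string q = as<std::string>(queries[i]);
    touched.clear();
    for (int pass = 0; pass < 2; ++pass) {
      kms.clear();
      enumerate_kmers(pass == 0 ? q : revcomp(q), k, kms);
      for (size_t t = 0; t < kms.size(); ++t) {
        std::unordered_map<uint64_t, std::vector<int> >::const_iterator it =
            index.find(kms[t].first);
        if (it == index.end()) continue;
        for (size_t u = 0; u < it->second.size(); ++u) {
          int j = it->second[u];
          if (!seen[j]) { seen[j] = 1; touched.push_back(j); }
        }
      }
    }
    std::sort(touched.begin(), touched.end());
    for (size_t t = 0; t < touched.size(); ++t) {
      qi.push_back(i + 1);
      si.push_back(touched[t] + 1);
      seen[touched[t]] = 0;
    }
  }
  IntegerMatrix out((int)qi.size(), 2);
  for (size_t t = 0; t < qi.size(); ++t) {
    out(t, 0) = qi[t];
    out(t, 1) = si[t];
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
std::string revcomp_cpp(std::string s) { return revcomp(s); }

// Best local alignment per fragment against a set of subject contigs,
// with the subject k-mer index built once (the aligner above re-indexes
// per call, which is wasteful for fragment-based ANI where hundreds of
// fragments query the same genome). Returns per-fragment best score,
// identity count and column count (0/0/0 when nothing aligns).
// [[Rcpp::export(name = ".best_fragment_hits_cpp")]]
DataFrame best_fragment_hits_cpp(CharacterVector fragments,
                                 CharacterVector subject_contigs, int k,
                                 int match, int mismatch, int gap_open,
                                 int gap_extend, int band, int margin) {
  const int nc = subject_contigs.size();
  std::vector<std::string> contigs(nc);
  std::vector<std::unordered_map<uint64_t, std::vector<int> > > index(nc);
  std::vector<std::pair<uint64_t, int> > kms;
  for (int c = 0; c < nc; ++c) {
    contigs[c] = as<std::string>(subject_contigs[c]);
    kms.clear();
    enumerate_kmers(contigs[c], k, kms);
    index[c].reserve(kms.size() * 2);
    for (size_t t = 0; t < kms.size(); ++t)
      index[c][kms[t].first].push_back(kms[t].second);
  }

  const int nf = fragments.size();
  IntegerVector best_score(nf), best_ident(nf), best_cols(nf);
  const size_t occ_cap = 64;
  const int cluster_gap = std::max(margin, 200);
  for (int f = 0; f < nf; ++f) {
    std::string frag = as<std::string>(fragments[f]);
    Aln best; best.score = 0; best.ident = 0; best.cols = 0;
    for (int pass = 0; pass < 2; ++pass) {
      std::string q = pass == 0 ? frag : revcomp(frag);
      kms.clear();
      enumerate_kmers(q, k, kms);
      for (int c = 0; c < nc; ++c) {
        std::vector<Seed> seeds;
        for (size_t t = 0; t < kms.size(); ++t) {
          std::unordered_map<uint64_t, std::vector<int> >::const_iterator
              it = index[c].find(kms[t].first);
          if (it == index[c].end() || it->second.size() > occ_cap) continue;
          for (size_t u = 0; u < it->second.size(); ++u) {
            Seed sd; sd.q = kms[t].second; sd.s = it->second[u];
            sd.d = sd.s - sd.q;
            seeds.push_back(sd);
          }
        }
        if (seeds.empty()) continue;
        std::sort(seeds.begin(), seeds.end(),
                  [](const Seed& a, const Seed& b) {
                    if (a.d != b.d) return a.d < b.d;
                    return a.s < b.s;
                  });
        struct Cluster { int dlo, dhi, qlo, qhi, slo, shi; };
        std::vector<Cluster> clusters;
        for (size_t t = 0; t < seeds.size(); ++t) {
          const Seed& sd = seeds[t];
          bool merged = false;
          if (!clusters.empty()) {
            Cluster& cl = clusters.back();
            if (sd.d - cl.dhi <= band && sd.s - cl.shi <= cluster_gap) {
              cl.dhi = std::max(cl.dhi, sd.d);
              cl.qlo = std::min(cl.qlo, sd.q); cl.qhi = std::max(cl.qhi, sd.q);
              cl.slo = std::min(cl.slo, sd.s); cl.shi = std::max(cl.shi, sd.s);
              merged = true;
            }
          }
          if (!merged) {
            Cluster cl; cl.dlo = cl.dhi = sd.d;
            cl.qlo = cl.qhi = sd.q; cl.slo = cl.shi = sd.s;
            clusters.push_back(cl);
          }
        }
        const int qn = (int)q.size(), sn = (int)contigs[c].size();
        for (size_t t = 0; t < clusters.size(); ++t) {
          const Cluster& cl = clusters[t];
          int q0 = std::max(0, cl.qlo - margin);
          int q1 = std::min(qn, cl.qhi + k + margin);
          int s0 = std::max(0, cl.slo - margin);
          int s1 = std::min(sn, cl.shi + k + margin);
          int dlo = (cl.dlo - (s0 - q0)) - band;
          int dhi = (cl.dhi - (s0 - q0)) + band;
          Aln a = banded_sw(q, contigs[c], q0, q1, s0, s1, dlo, dhi, match,
                            mismatch, gap_open, gap_extend);
          if (a.score > best.score) best = a;
        }
      }
    }
    best_score[f] = best.score;
    best_ident[f] = best.ident;
    best_cols[f] = best.cols;
  }
  return DataFrame::create(_["score"] = best_score, _["n_ident"] = best_ident,
                           _["aln_length"] = best_cols);
}
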