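#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// 2-bit base encoding; anything not ACGT (upper case) is invalid and breaks
// the rolling k-mer.
static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

// Enumerate valid k-mers of seq as (kmer, position) using a rolling 2-bit code.
static void collect_kmers(const std::string &seq, int k,
                          std::vector<std::pair<uint64_t, uint32_t> > &out) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t code = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint64_t)b) & mask;
    if (++run >= k) out.push_back(std::make_pair(code, (uint32_t)(i + 1 - k)));
  }
}

struct Seed { int32_t q; int32_t t; };

// Chain seeds of one read strand against the indexed target set and append
// hit rows. Seeds are grouped by diagonal (t - q) bands, then split along the
// read where the gap exceeds max_gap, the target regresses, or the target
// sequence changes.
static void chain_strand(std::vector<Seed> &seeds,
                         const std::vector<int64_t> &tstarts, // global start per target
                         int k, int read_len, bool minus,
                         int min_hit_length, double min_identity,
                         int max_gap, int diag_band,
                         int read_index,
                         std::vector<int> &o_read, std::vector<int> &o_qs,
                         std::vector<int> &o_qe, std::vector<int> &o_tid,
                         std::vector<int> &o_ts, std::vector<int> &o_te,
                         std::vector<int> &o_strand, std::vector<double> &o_ident,
                         std::vector<int> &o_nseed) {
  if (seeds.empty()) return;
  std::sort(seeds.begin(), seeds.end(), [](const Seed &a, const Seed &b) {
    int64_t da = (int64_t)a.t - a.q, db = (int64_t)b.t - b.q;
    if (da != db) return da < db;
    return a.q < b.q;
  });
  size_t n = seeds.size();
  std::vector<size_t> grp_start;
  grp_start.push_back(0);
  for (size_t i = 1; i < n; ++i) {
    int64_t d0 = (int64_t)seeds[i - 1].t - seeds[i - 1].q;
    int64_t d1 = (int64_t)seeds[i].t - seeds[i].q;
    if (d1 - d0 > diag_band) grp_start.push_back(i);
  }
  grp_start.push_back(n);

  auto target_of = [&](int64_t gpos) {
    // index of last tstart <= gpos
    size_t lo = 0, hi = tstarts.size();
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if (tstarts[mid] <= gpos) lo = mid; else hi = mid;
    }
    return (int)lo;
  };

  std::vector<Seed> chain;
  for (size_t g = 0; g + 1 < grp_start.size(); ++g) {
    size_t s = grp_start[g], e = grp_start[g + 1];
    std::vector<Seed> grp(seeds.begin() + s, seeds.begin() + e);
    std::sort(grp.begin(), grp.end(), [](const Seed &a, const Seed &b) {
      if (a.q != b.q) return a.q < b.q;
      return a.t < b.t;
    });
    // split along read
    size_t i0 = 0;
    for (size_t i = 0; i <= grp.size(); ++i) {
      bool cut = (i == grp.size());
      if (!cut && i > i0) {
        const Seed &p = grp[i - 1], &c = grp[i];
        if (c.q - p.q > max_gap || c.t - p.t < -diag_band ||
            c.t - p.t > max_gap + diag_band ||
            target_of(c.t) != target_of(p.t))
          cut = true;
      }
      if (cut) {
        if (i > i0) {
          // Trim sparse terminal seeds: a genuine alignment ends in a
          // seed-dense region, while a lone errored k-mer matching the
          // target in-band by chance extends the chain past the true
          // boundary. Seeds more than 250 bp (read axis) from the rest of
          // the chain are dropped from both ends.
          const int trim = 250;
          size_t a = i0, b = i; // chain is grp[a, b)
          while (b - a >= 2 && grp[b - 1].q - grp[b - 2].q > trim) --b;
          while (b - a >= 2 && grp[a + 1].q - grp[a].q > trim) ++a;
          // emit chain grp[a, b)
          int m = 0;
          int32_t prevq = -1;
          int32_t tmin = grp[a].t, tmax = grp[a].t;
          for (size_t j = a; j < b; ++j) {
            if (grp[j].q != prevq) { ++m; prevq = grp[j].q; }
            if (grp[j].t < tmin) tmin = grp[j].t;
            if (grp[j].t > tmax) tmax = grp[j].t;
          }
          int qs = grp[a].q, qe = grp[b - 1].q + k;
          int span = qe - qs;
          int tspan = tmax + k - tmin;
          // A genuine hit of min_hit_length carries a dozen or more exact
          // k-mers even at 15% error; chains of a handful of seeds are
          // chance diagonal coincidences.
          if (m >= 5 && span >= min_hit_length && tspan >= min_hit_length) {
            int windows = span - k + 1;
            double f = (double)m / (double)windows;
            if (f > 1.0) f = 1.0;
            double ident = std::pow(f, 1.0 / (double)k);
            if (ident >= min_identity) {
              int tid = target_of(tmin);
              int ts = (int)(tmin - tstarts[tid]);
              int te = (int)(tmax + k - tstarts[tid]);
              int oqs = qs, oqe = qe;
              if (minus) { oqs = read_len - qe; oqe = read_len - qs; }
              o_read.push_back(read_index);
              o_qs.push_back(oqs); o_qe.push_back(oqe);
              o_tid.push_back(tid); o_ts.push_back(ts); o_te.push_back(te);
              o_strand.push_back(minus ? 1 : 0);
              o_ident.push_back(ident);
              o_nseed.push_back(m);
            }
          }
        }
        i0 = i;
        if (!cut && i < grp.size()) i0 = i;
      }
    }
  }
  (void)chain;
}

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export(name = ".cpp_kmer_map")]]
DataFrame cpp_kmer_map(CharacterVector reads, CharacterVector targets,
                       int k, int min_hit_length, double min_identity,
                       int max_gap, int diag_band, int max_occ) {
  // Index: (kmer, global position) pairs over all targets, separated by
  // virtual gaps so no k-mer spans two targets; grouped by key and exposed
  // through an open-addressing hash table for O(1) lookup.
  std::vector<std::pair<uint64_t, uint32_t> > idx;
  std::vector<int64_t> tstarts;
  {
    int64_t off = 0;
    size_t total = 0;
    for (int i = 0; i < targets.size(); ++i) total += LENGTH(STRING_ELT(targets, i));
    idx.reserve(total);
    for (int i = 0; i < targets.size(); ++i) {
      std::string t = as<std::string>(targets[i]);
      tstarts.push_back(off);
      std::vector<std::pair<uint64_t, uint32_t> > kk;
      collect_kmers(t, k, kk);
      for (size_t j = 0; j < kk.size(); ++j)
        idx.push_back(std::make_pair(kk[j].first, (uint32_t)(off + kk[j].second)));
      off += (int64_t)t.size() + k + 1; // gap so adjacent targets never chain
    }
  }
  std::sort(idx.begin(), idx.end());
  // unique keys + position ranges
  std::vector<uint64_t> ukey;
  std::vector<uint32_t> ustart;
  ukey.reserve(idx.size()); ustart.reserve(idx.size() + 1);
  for (size_t i = 0; i < idx.size(); ++i) {
    if (i == 0 || idx[i].first != idx[i - 1].first) {
      ukey.push_back(idx[i].first);
      ustart.push_back((uint32_t)i);
    }
  }
  ustart.push_back((uint32_t)idx.size());
  // hash table: slot -> index into ukey
  size_t S = 1;
  while (S < 2 * ukey.size() + 2) S <<= 1;
  std::vector<int32_t> slot(S, -1);
  for (size_t i = 0; i < ukey.size(); ++i) {
    size_t h = mix64(ukey[i]) & (S - 1);
    while (slot[h] >= 0) h = (h + 1) & (S - 1);
    slot[h] = (int32_t)i;
  }
  auto lookup = [&](uint64_t key) -> int32_t {
    size_t h = mix64(key) & (S - 1);
    while (slot[h] >= 0) {
      if (ukey[slot[h]] == key) return slot[h];
      h = (h + 1) & (S - 1);
    }
    return -1;
  };

  std::vector<int> o_read, o_qs, o_qe, o_tid, o_ts, o_te, o_strand, o_nseed;
  std::vector<double> o_ident;

  std::vector<std::pair<uint64_t, uint32_t> > rk;
  std::vector<Seed> seeds;
  for (int r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int rl = (int)fwd.size();
    std::string rc(fwd.rbegin(), fwd.rend());
    for (size_t i = 0; i < rc.size(); ++i) rc[i] = complement(rc[i]);
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &s = strand ? rc : fwd;
      rk.clear();
      collect_kmers(s, k, rk);
      seeds.clear();
      for (size_t i = 0; i < rk.size(); ++i) {
        int32_t u = lookup(rk[i].first);
        if (u < 0) continue;
        uint32_t lo = ustart[u], hi = ustart[u + 1];
        if (hi - lo > (uint32_t)max_occ) continue;
        for (uint32_t j = lo; j < hi; ++j) {
          Seed sd; sd.q = (int32_t)rk[i].second; sd.t = (int32_t)idx[j].second;
          seeds.push_back(sd);
        }
      }
      chain_strand(seeds, tstarts, k, rl, strand == 1,
                   min_hit_length, min_identity, max_gap, diag_band, r + 1,
                   o_read, o_qs, o_qe, o_tid, o_ts, o_te, o_strand, o_ident,
                   o_nseed);
    }
  }

  return DataFrame::create(
    Named("read") = wrap(o_read),
    Named("read_start") = wrap(o_qs),
    Named("read_end") = wrap(o_qe),
    Named("target") = wrap(o_tid),
    Named("target_start") = wrap(o_ts),
    Named("target_end") = wrap(o_te),
    Named("minus") = wrap(o_strand),
    Named("identity") = wrap(o_ident),
    Named("n_seeds") = wrap(o_nseed));
}

// [[Rcpp::export(name = ".cpp_mutate")]]
CharacterVector cpp_mutate(CharacterVector seqs, double sub_rate,
                           double ins_rate, double del_rate) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  RNGScope scope;
  CharacterVector out(seqs.size());
  std::string buf;
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    buf.clear();
    buf.reserve((size_t)(s.size() * (1.0 + ins_rate) + 16));
    for (size_t j = 0; j < s.size(); ++j) {
      double u = unif_rand();
      if (u < del_rate) {
        // deleted
      } else if (u < del_rate + sub_rate) {
        int b0 = base2bits(s[j]);
        int b = (int)(unif_rand() * 3.0);
        if (b > 2) b = 2;
        if (b0 >= 0) b = (b0 + 1 + b) % 4; // any base but the original
        buf.push_back(bases[b]);
      } else {
        buf.push_back(s[j]);
      }
      if (unif_rand() < ins_rate) {
        int b = (int)(unif_rand() * 4.0);
        if (b > 3) b = 3;
        buf.push_back(bases[b]);
      }
    }
    out[i] = buf;
  }
  return out;
}
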