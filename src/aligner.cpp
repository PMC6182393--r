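// Seed-and-extend local read aligner for paralogous reference sets.
//
// Exact k-mer seeds (default k = 15, both strands) locate candidate
// diagonals per reference; each diagonal cluster is then resolved with a
// banded Smith-Waterman (linear gap penalty) and the best-scoring local
// alignment per read/reference pair is reported with match counts, so
// identity = matches / alignment_length can be thresholded downstream.

#include <Rcpp.h>
#include <unordered_map>
#include <map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int enc(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'a': c = 'T'; break;
      case 'C': c = 'G'; break; case 'c': c = 'G'; break;
      case 'G': c = 'C'; break; case 'g': c = 'C'; break;
      case 'T': c = 'A'; break; case 't': c = 'A'; break;
      default: c = 'N';
    }
  }
  return r;
}

struct AlnResult {
  int score = 0, matches = 0, alnlen = 0;
  int read_start = 0, read_end = 0, ref_start = 0, ref_end = 0;
};

// Banded local alignment of a (read) vs b (ref); diagonals d = j - i
// restricted to [dlo, dhi] (1-based i over a, j over b).
static AlnResult banded_sw(const std::string &a, const std::string &b,
                           int dlo, int dhi,
                           int match, int mismatch, int gap) {
  const int m = (int)a.size(), n = (int)b.size();
  if (dlo < 1 - m) dlo = 1 - m;
  if (dhi > n - 1) dhi = n - 1;
  if (dlo > dhi) return AlnResult();
  const int W = dhi - dlo + 1;
  std::vector<int> H((size_t)(m + 1) * W, 0);
  std::vector<uint8_t> D((size_t)(m + 1) * W, 0);  // 0 stop, 1 diag, 2 up, 3 left
  int best = 0, bi = 0, bw = 0;
  for (int i = 1; i <= m; ++i) {
    for (int w = 0; w < W; ++w) {
      const int j = i + dlo + w;
      if (j < 1 || j > n) continue;
      const int sub = (enc(a[(size_t)i - 1]) >= 0 &&
                       enc(a[(size_t)i - 1]) == enc(b[(size_t)j - 1]))
                          ? match : mismatch;
      int v = 0; uint8_t dd = 0;
      // diagonal: H(i-1, j-1) -> same w at row i-1
      int cand = H[(size_t)(i - 1) * W + w] + sub;
      if (cand > v) { v = cand; dd = 1; }
      // up: H(i-1, j) -> w + 1 at row i-1 (gap in ref)
      if (w + 1 < W && j >= 1) {
        cand = H[(size_t)(i - 1) * W + w + 1] + gap;
        if (cand > v) { v = cand; dd = 2; }
      }
      // left: H(i, j-1) -> w - 1 at row i (gap in read)
      if (w - 1 >= 0 && j - 1 >= 1) {
        cand = H[(size_t)i * W + w - 1] + gap;
        if (cand > v) { v = cand; dd = 3; }
      }
      H[(size_t)i * W + w] = v;
      D[(size_t)i * W + w] = (v > 0) ? dd : 0;
      if (v > best) { best = v; bi = i; bw = w; }
    }
  }
  AlnResult res;
  if (best <= 0) return res;
  res.score = best;
  // traceback
  int i = bi, w = bw;
  res.read_end = bi;
  res.ref_end = bi + dlo + bw;
  int matches = 0, alnlen = 0;
  while (i > 0 && H[(size_t)i * W + w] > 0) {
    const uint8_t dd = D[(size_t)i * W + w];
    if (dd == 0) break;
    const int j = i + dlo + w;
    if (dd == 1) {
      ++alnlen;
      if (enc(a[(size_t)i - 1]) >= 0 &&
          enc(a[(size_t)i - 1]) == enc(b[(size_t)j - 1])) ++matches;
      i -= 1;  // w unchanged
    } else if (dd == 2) {
      ++alnlen;
      i -= 1; w += 1;
    } else {
      ++alnlen;
      w -= 1;
    }
  }
  res.read_start = i + 1;
  res.ref_start = i + dlo + w + 1;
  res.matches = matches;
  res.alnlen = alnlen;
  return res;
}

// [[Rcpp::export]]
DataFrame align_reads_cpp(CharacterVector reads, CharacterVector refs,
                          int k, double min_identity, int min_aln_len,
                          int band, int match, int mismatch, int gap) {
  const int R = refs.size();
  std::vector<std::string> ref_seq(R);
  for (int r = 0; r < R; ++r) ref_seq[r] = as<std::string>(refs[r]);

  // k-mer index over the references (forward strand only; reads searched
  // on both strands instead)
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> index;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < R; ++r) {
    const std::string &s = ref_seq[r];
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      const int c = enc(s[(size_t)p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[key].push_back({r, p - k + 1});
    }
  }

  std::vector<std::string> out_read, out_ref, out_strand;
  std::vector<int> out_score, out_matches, out_len;
  std::vector<int> out_rs, out_re, out_gs, out_ge;
  std::vector<double> out_id;

  CharacterVector read_names = reads.names();
  CharacterVector ref_names = refs.names();

  for (int q = 0; q < reads.size(); ++q) {
    const std::string fwd = as<std::string>(reads[q]);
    const std::string rev = revcomp_str(fwd);
    const int m = (int)fwd.size();
    // best per reference over strands and clusters
    std::map<int, std::pair<AlnResult, int>> best;  // ref -> (result, strand)
    for (int st = 0; st < 2; ++st) {
      const std::string &rd = (st == 0) ? fwd : rev;
      std::map<int, std::vector<int>> diags;
      uint64_t key = 0; int run = 0;
      for (int p = 0; p < (int)rd.size(); ++p) {
        const int c = enc(rd[(size_t)p]);
        if (c < 0) { run = 0; key = 0; continue; }
        key = ((key << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          auto it = index.find(key);
          if (it != index.end()) {
            const int pr = p - k + 1;
            for (const auto &hit : it->second) {
              diags[hit.first].push_back(hit.second - pr);
            }
          }
        }
      }
      for (auto &kv : diags) {
        const int r = kv.first;
        std::vector<int> &ds = kv.second;
        std::sort(ds.begin(), ds.end());
        ds.erase(std::unique(ds.begin(), ds.end()), ds.end());
        size_t c0 = 0;
        for (size_t i2 = 1; i2 <= ds.size(); ++i2) {
          if (i2 == ds.size() || ds[i2] - ds[i2 - 1] > band) {
            const int dlo = ds[c0] - band, dhi = ds[i2 - 1] + band;
            AlnResult res = banded_sw(rd, ref_seq[(size_t)r], dlo, dhi,
                                      match, mismatch, gap);
            auto it = best.find(r);
            if (it == best.end() || res.score > it->second.first.score) {
              best[r] = {res, st};
            }
            c0 = i2;
          }
        }
      }
    }
    for (const auto &kv : best) {
      const AlnResult &res = kv.second.first;
      if (res.score <= 0 || res.alnlen < min_aln_len) continue;
      const double id = (double)res.matches / (double)res.alnlen;
      if (id < min_identity) continue;
      int rs = res.read_start, re = res.read_end;
      if (kv.second.second == 1) {  // convert to forward-read coordinates
        rs = m - res.read_end + 1;
        re = m - res.read_start + 1;
      }
      out_read.push_back(as<std::string>(read_names[q]));
      out_ref.push_back(as<std::string>(ref_names[kv.first]));
      out_strand.push_back(kv.second.second == 0 ? "+" : "-");
      out_score.push_back(res.score);
      out_matches.push_back(res.matches);
      out_len.push_back(res.alnlen);
      out_id.push_back(id);
      out_rs.push_back(rs);
      out_re.push_back(re);
      out_gs.push_back(res.ref_start);
      out_ge.push_back(res.ref_end);
    }
  }

  return DataFrame::create(
    _["read_id"] = out_read, _["gene_id"] = out_ref, _["strand"] = out_strand,
    _["score"] = out_score, _["matches"] = out_matches,
    _["aln_len"] = out_len, _["identity"] = out_id,
    _["read_start"] = out_rs, _["read_end"] = out_re,
    _["ref_start"] = out_gs, _["ref_end"] = out_ge,
    _["stringsAsFactors"] = false);
}
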