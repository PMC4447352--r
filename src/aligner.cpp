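// Seed-and-extend nucleotide similarity search.
//
// Per query/subject pair sharing an exact word_size seed:
//   1. ungapped X-drop extension from one seed per diagonal (cheap filter)
//   2. if the best ungapped score reaches trigger_score, an affine-gap local
//      alignment with traceback, computed over the diagonal band spanned by
//      the pair's seeds plus band_pad on each side (out-of-band cells are
//      treated as fresh zero-score starts, so the banded score is always a
//      valid local-alignment score and never exceeds the unbanded optimum;
//      it equals it whenever the optimal path stays inside the band). A gap
//      of length L costs gap_open + L * gap_ext, the convention of
//      Biostrings::pairwiseAlignment.
//   3. Karlin-Altschul e-value E = K * m * n * exp(-lambda * S) with n the
//      total residue count of the subject set.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static std::vector<int8_t> encode_seq(const std::string& s) {
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 0; break;
      case 'C': v[i] = 1; break;
      case 'G': v[i] = 2; break;
      case 'T': v[i] = 3; break;
      default:  v[i] = -1; break;  // N and anything else: never matches
    }
  }
  return v;
}

static std::vector<int8_t> revcomp_enc(const std::vector<int8_t>& v) {
  std::vector<int8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    int8_t b = v[v.size() - 1 - i];
    r[i] = (b < 0) ? -1 : (3 - b);
  }
  return r;
}

struct SWResult {
  double score;
  int matches, aln_len;
  int q_start, q_end, s_start, s_end;  // 0-based half-open
};

// Affine-gap local alignment restricted to diagonals i - j in [dlo, dhi],
// with full traceback. dlo <= dhi; pass dlo = -(n), dhi = m for the
// unrestricted matrix.
static SWResult banded_sw(const std::vector<int8_t>& a,
                          const std::vector<int8_t>& b,
                          int dlo, int dhi,
                          double match, double mismatch,
                          double gap_open, double gap_ext,
                          std::vector<uint8_t>& tbH,
                          std::vector<uint8_t>& tbE,
                          std::vector<uint8_t>& tbF) {
  const int m = (int)a.size(), n = (int)b.size();
  const double NEG = -1e30;
  std::vector<double> H(n + 1, 0.0), Fcol(n + 1, NEG);
  size_t cells = (size_t)(m + 1) * (n + 1);
  tbH.assign(cells, 0);
  tbE.assign(cells, 0);
  tbF.assign(cells, 0);
  double best = 0.0; int bi = 0, bj = 0;
  int prev_jhi = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i - dhi);
    int jhi = std::min(n, i - dlo);
    if (jlo > jhi) continue;
    // cells newly entering the band on the right edge carry stale state
    if (jhi > prev_jhi) {
      for (int j = std::max(jlo, prev_jhi + 1); j <= jhi; ++j) {
        H[j] = 0.0; Fcol[j] = NEG;
      }
    }
    double Hdiag = H[jlo - 1];
    if (jlo == 1) H[0] = 0.0;
    double Ei = NEG;
    size_t row = (size_t)i * (n + 1);
    for (int j = jlo; j <= jhi; ++j) {
      double e_open = H[j - 1] - gap_open - gap_ext;
      double e_ext  = Ei - gap_ext;
      Ei = (e_ext > e_open) ? e_ext : e_open;
      tbE[row + j] = (e_ext > e_open) ? 1 : 0;
      double f_open = H[j] - gap_open - gap_ext;
      double f_ext  = Fcol[j] - gap_ext;
      Fcol[j] = (f_ext > f_open) ? f_ext : f_open;
      tbF[row + j] = (f_ext > f_open) ? 1 : 0;
      bool mt = (a[i - 1] >= 0) && (a[i - 1] == b[j - 1]);
      double diag = Hdiag + (mt ? match : mismatch);
      double h = 0.0; uint8_t code = 0;
      if (diag > h) { h = diag; code = 1; }
      if (Ei > h)   { h = Ei;   code = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; code = 3; }
      Hdiag = H[j];
      H[j] = h;
      tbH[row + j] = code;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    // the left edge cell leaving the band must read as out-of-band (H = 0)
    // for the next row's diagonal move
    if (jlo > 1) H[jlo - 1] = 0.0;
    prev_jhi = jhi;
  }
  SWResult res{best, 0, 0, 0, 0, 0, 0};
  if (best <= 0.0) return res;
  int i = bi, j = bj, state = 0;
  res.q_end = bi; res.s_end = bj;
  while (true) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      uint8_t c = tbH[idx];
      if (c == 0) break;
      if (c == 1) {
        res.aln_len++;
        if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) res.matches++;
        --i; --j;
      } else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      res.aln_len++;
      if (tbE[idx] == 0) state = 0;
      --j;
    } else {
      res.aln_len++;
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }
  res.q_start = i; res.s_start = j;
  return res;
}

// Ungapped X-drop extension from an exact seed.
static double xdrop_ungapped(const std::vector<int8_t>& a,
                             const std::vector<int8_t>& b,
                             int qpos, int spos, int word,
                             double match, double mismatch, double x_drop) {
  double score = word * match;
  double run = 0.0, bestr = 0.0;
  int i = qpos + word, j = spos + word;
  while (i < (int)a.size() && j < (int)b.size()) {
    run += (a[i] >= 0 && a[i] == b[j]) ? match : mismatch;
    if (run > bestr) bestr = run;
    if (run < bestr - x_drop) break;
    ++i; ++j;
  }
  double bestl = 0.0;
  run = 0.0;
  i = qpos - 1; j = spos - 1;
  while (i >= 0 && j >= 0) {
    run += (a[i] >= 0 && a[i] == b[j]) ? match : mismatch;
    if (run > bestl) bestl = run;
    if (run < bestl - x_drop) break;
    --i; --j;
  }
  return score + bestr + bestl;
}

struct Seed { int sj; int strand; int diag; int qpos; int spos; };

// [[Rcpp::export]]
DataFrame cpp_similarity_search(CharacterVector query_seqs,
                                CharacterVector subject_seqs,
                                bool self, int word_size, double max_evalue,
                                double match, double mismatch,
                                double gap_open, double gap_ext,
                                double lambda, double K,
                                double x_drop, double trigger_score,
                                bool search_rc, int band_pad) {
  const int nq = query_seqs.size(), ns = subject_seqs.size();
  if (word_size < 4 || word_size > 15) stop("word_size must be in [4, 15]");
  std::vector<std::vector<int8_t>> qenc(nq), senc(ns), src(ns);
  double db_residues = 0.0;
  for (int i = 0; i < nq; ++i) qenc[i] = encode_seq(as<std::string>(query_seqs[i]));
  for (int j = 0; j < ns; ++j) {
    senc[j] = encode_seq(as<std::string>(subject_seqs[j]));
    if (search_rc) src[j] = revcomp_enc(senc[j]);
    db_residues += (double)senc[j].size();
  }

  const uint32_t mask = (1u << (2 * word_size)) - 1u;
  typedef std::unordered_map<uint32_t, std::vector<std::pair<int,int>>> Index;
  Index idx_plus, idx_minus;
  auto index_set = [&](const std::vector<std::vector<int8_t>>& seqs, Index& idx) {
    for (int j = 0; j < (int)seqs.size(); ++j) {
      const std::vector<int8_t>& s = seqs[j];
      uint32_t w = 0; int run = 0;
      for (int p = 0; p < (int)s.size(); ++p) {
        if (s[p] < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint32_t)s[p]) & mask;
        if (++run >= word_size) idx[w].push_back({j, p - word_size + 1});
      }
    }
  };
  index_set(senc, idx_plus);
  if (search_rc) index_set(src, idx_minus);

  std::vector<int> out_q, out_s, out_qs, out_qe, out_ss, out_se, out_len;
  std::vector<double> out_score, out_eval, out_bit, out_ident;
  std::vector<int> out_strand;
  std::vector<uint8_t> tbH, tbE, tbF;  // reused across pairs
  std::vector<Seed> cand;

  for (int qi = 0; qi < nq; ++qi) {
    const std::vector<int8_t>& q = qenc[qi];
    cand.clear();
    auto scan = [&](Index& idx, int strand) {
      uint32_t w = 0; int run = 0;
      for (int p = 0; p < (int)q.size(); ++p) {
        if (q[p] < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint32_t)q[p]) & mask;
        if (++run < word_size) continue;
        auto it = idx.find(w);
        if (it == idx.end()) continue;
        int qpos = p - word_size + 1;
        for (auto& hit : it->second) {
          if (self && hit.first <= qi) continue;  // each pair handled once
          cand.push_back({hit.first, strand, qpos - hit.second,
                          qpos, hit.second});
        }
      }
    };
    scan(idx_plus, 0);
    if (search_rc) scan(idx_minus, 1);
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end(), [](const Seed& x, const Seed& y) {
      if (x.sj != y.sj) return x.sj < y.sj;
      if (x.strand != y.strand) return x.strand < y.strand;
      return x.diag < y.diag;
    });
    size_t lo = 0;
    while (lo < cand.size()) {
      size_t hi = lo;
      while (hi < cand.size() && cand[hi].sj == cand[lo].sj &&
             cand[hi].strand == cand[lo].strand) ++hi;
      int sj = cand[lo].sj, strand = cand[lo].strand;
      const std::vector<int8_t>& b = (strand == 0) ? senc[sj] : src[sj];
      // one X-drop probe per distinct diagonal
      double best_ungapped = 0.0;
      int dmin = cand[lo].diag, dmax = cand[hi - 1].diag;
      int last_diag = INT32_MIN;
      for (size_t t = lo; t < hi; ++t) {
        if (cand[t].diag == last_diag) continue;
        last_diag = cand[t].diag;
        double sc = xdrop_ungapped(q, b, cand[t].qpos, cand[t].spos,
                                   word_size, match, mismatch, x_drop);
        if (sc > best_ungapped) best_ungapped = sc;
        if (best_ungapped >= trigger_score) break;
      }
      lo = hi;
      if (best_ungapped < trigger_score) continue;
      SWResult r = banded_sw(q, b, dmin - band_pad, dmax + band_pad,
                             match, mismatch, gap_open, gap_ext,
                             tbH, tbE, tbF);
      if (r.score <= 0.0) continue;
      int s_start = r.s_start, s_end = r.s_end;
      if (strand == 1) {  // map back to the subject's forward strand
        int L = (int)b.size();
        int fs = L - s_end, fe = L - s_start;
        s_start = fs; s_end = fe;
      }
      double expterm = std::exp(-lambda * r.score);
      double e_fwd = K * (double)q.size() * db_residues * expterm;
      double bit = (lambda * r.score - std::log(K)) / std::log(2.0);
      double ident = (r.aln_len > 0) ? (double)r.matches / (double)r.aln_len : 0.0;
      if (e_fwd <= max_evalue) {
        out_q.push_back(qi + 1); out_s.push_back(sj + 1);
        out_score.push_back(r.score); out_eval.push_back(e_fwd);
        out_bit.push_back(bit); out_ident.push_back(ident);
        out_qs.push_back(r.q_start); out_qe.push_back(r.q_end);
        out_ss.push_back(s_start); out_se.push_back(s_end);
        out_len.push_back(r.aln_len); out_strand.push_back(strand);
      }
      if (self) {  // mirrored direction of the same alignment
        double e_rev = K * (double)senc[sj].size() * db_residues * expterm;
        if (e_rev <= max_evalue) {
          out_q.push_back(sj + 1); out_s.push_back(qi + 1);
          out_score.push_back(r.score); out_eval.push_back(e_rev);
          out_bit.push_back(bit); out_ident.push_back(ident);
          out_qs.push_back(s_start); out_qe.push_back(s_end);
          out_ss.push_back(r.q_start); out_se.push_back(r.q_end);
          out_len.push_back(r.aln_len); out_strand.push_back(strand);
        }
      }
    }
  }

  return DataFrame::create(
    _["q_idx"] = out_q, _["s_idx"] = out_s, _["score"] = out_score,
    _["evalue"] = out_eval, _["bitscore"] = out_bit,
    _["identity"] = out_ident, _["q_start"] = out_qs, _["q_end"] = out_qe,
    _["s_start"] = out_ss, _["s_end"] = out_se,
    _["aligned_length"] = out_len, _["strand"] = out_strand,
    _["stringsAsFactors"] = false);
}

// One EM run for a univariate Gaussian mixture with unequal variances.
// Returns the fitted parameters, the final log-likelihood and the
// per-iteration log-likelihood trace.
// [[Rcpp::export]]
List cpp_em_gmm(NumericVector x, NumericVector mu0, NumericVector sd0,
                NumericVector w0, double tol, int max_iter, double sd_floor) {
  const int n = x.size(), k = mu0.size();
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> sd(sd0.begin(), sd0.end());
  std::vector<double> w(w0.begin(), w0.end());
  for (int j = 0; j < k; ++j) if (sd[j] < sd_floor) sd[j] = sd_floor;
  const double LOG2PI = std::log(2.0 * M_PI);
  std::vector<double> resp((size_t)n * k);
  std::vector<double> logc(k);
  std::vector<double> trace;
  trace.reserve(64);
  double ll_old = -std::numeric_limits<double>::infinity();
  auto loglik_pass = [&](bool fill_resp) {
    for (int j = 0; j < k; ++j)
      logc[j] = std::log(w[j]) - std::log(sd[j]) - 0.5 * LOG2PI;
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mrow = -std::numeric_limits<double>::infinity();
      for (int j = 0; j < k; ++j) {
        double z = (x[i] - mu[j]) / sd[j];
        double ld = logc[j] - 0.5 * z * z;
        resp[(size_t)i * k + j] = ld;
        if (ld > mrow) mrow = ld;
      }
      double s = 0.0;
      for (int j = 0; j < k; ++j) s += std::exp(resp[(size_t)i * k + j] - mrow);
      double lse = mrow + std::log(s);
      ll += lse;
      if (fill_resp)
        for (int j = 0; j < k; ++j)
          resp[(size_t)i * k + j] = std::exp(resp[(size_t)i * k + j] - lse);
    }
    return ll;
  };
  for (int iter = 0; iter < max_iter; ++iter) {
    double ll = loglik_pass(true);
    trace.push_back(ll);
    // M step
    for (int j = 0; j < k; ++j) {
      double nk = 0.0, sx = 0.0, sxx = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = resp[(size_t)i * k + j];
        nk += r; sx += r * x[i]; sxx += r * x[i] * x[i];
      }
      if (nk < 1e-12) nk = 1e-12;
      w[j] = nk / n;
      mu[j] = sx / nk;
      double v = sxx / nk - mu[j] * mu[j];
      sd[j] = std::sqrt(v > 0.0 ? v : 0.0);
      if (sd[j] < sd_floor) sd[j] = sd_floor;
    }
    if (std::isfinite(ll_old) &&
        std::fabs(ll - ll_old) < tol * (std::fabs(ll_old) + 1.0)) break;
    ll_old = ll;
  }
  double ll_final = loglik_pass(false);
  trace.push_back(ll_final);
  return List::create(_["weights"] = w, _["means"] = mu, _["sds"] = sd,
                      _["loglik"] = ll_final, _["trace"] = trace);
}

// Global (Needleman-Wunsch) alignment of two protein sequences under a
// substitution matrix with affine gaps (gap of length L costs
// gap_open + L * gap_ext), back-mapped to the coding nucleotide sequences so
// every residue gap becomes a 3-nt gap. Returns the two gapped nucleotide
// strings and the protein alignment score.
// [[Rcpp::export]]
List cpp_codon_align(std::string prot_a, std::string prot_b,
                     std::string orf_a, std::string orf_b,
                     NumericMatrix submat, double gap_open, double gap_ext) {
  // residue -> matrix row lookup from dimnames
  CharacterVector rn = rownames(submat);
  int lut[256];
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  const int m = (int)prot_a.size(), n = (int)prot_b.size();
  auto sub = [&](int i, int j) {
    int ri = lut[(unsigned char)prot_a[i]], rj = lut[(unsigned char)prot_b[j]];
    if (ri < 0 || rj < 0) stop("residue not in substitution matrix");
    return submat(ri, rj);
  };
  const double NEG = -1e30;
  std::vector<double> H(n + 1), E(n + 1);
  std::vector<uint8_t> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 0);
  H[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    H[j] = -gap_open - gap_ext * j;
    E[j] = NEG;
    tbH[j] = 2;
    tbE[j] = (j > 1) ? 1 : 0;
  }
  std::vector<double> Fcol(n + 1, NEG);
  for (int i = 1; i <= m; ++i) {
    double Hdiag = H[0];
    H[0] = -gap_open - gap_ext * i;
    size_t row = (size_t)i * (n + 1);
    tbH[row] = 3;
    tbF[row] = (i > 1) ? 1 : 0;
    double Ei = NEG;
    for (int j = 1; j <= n; ++j) {
      double e_open = H[j - 1] - gap_open - gap_ext;
      double e_ext  = Ei - gap_ext;
      Ei = (e_ext > e_open) ? e_ext : e_open;
      tbE[row + j] = (e_ext > e_open) ? 1 : 0;
      double f_open = H[j] - gap_open - gap_ext;
      double f_ext  = Fcol[j] - gap_ext;
      Fcol[j] = (f_ext > f_open) ? f_ext : f_open;
      tbF[row + j] = (f_ext > f_open) ? 1 : 0;
      double diag = Hdiag + sub(i - 1, j - 1);
      double h = diag; uint8_t code = 1;
      if (Ei > h)   { h = Ei;   code = 2; }
      if (Fcol[j] > h) { h = Fcol[j]; code = 3; }
      Hdiag = H[j];
      H[j] = h;
      tbH[row + j] = code;
    }
  }
  double score = H[n];
  // traceback into gapped protein index strings
  std::string ga, gb;
  ga.reserve(m + n); gb.reserve(m + n);
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      uint8_t c = tbH[idx];
      if (c == 1) { ga.push_back('A'); gb.push_back('B'); --i; --j; }
      else if (c == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ga.push_back('-'); gb.push_back('B');
      if (tbE[idx] == 0) state = 0;
      --j;
    } else {
      ga.push_back('A'); gb.push_back('-');
      if (tbF[idx] == 0) state = 0;
      --i;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  // back-map to nucleotides
  std::string nt_a, nt_b;
  nt_a.reserve(3 * ga.size()); nt_b.reserve(3 * gb.size());
  size_t pa = 0, pb = 0;
  for (size_t t = 0; t < ga.size(); ++t) {
    if (ga[t] == '-') nt_a += "---";
    else { nt_a.append(orf_a, 3 * pa, 3); ++pa; }
    if (gb[t] == '-') nt_b += "---";
    else { nt_b.append(orf_b, 3 * pb, 3); ++pb; }
  }
  return List::create(_["aligned_a"] = nt_a, _["aligned_b"] = nt_b,
                      _["score"] = score);
}

// Exact (unbanded) local alignment of one sequence pair, exposed for direct
// use and for oracle comparisons.
// [[Rcpp::export]]
List cpp_sw_pair(std::string a, std::string b, double match, double mismatch,
                 double gap_open, double gap_ext) {
  std::vector<int8_t> ea = encode_seq(a), eb = encode_seq(b);
  std::vector<uint8_t> tbH, tbE, tbF;
  SWResult r = banded_sw(ea, eb, -(int)eb.size(), (int)ea.size(),
                         match, mismatch, gap_open, gap_ext, tbH, tbE, tbF);
  return List::create(
    _["score"] = r.score, _["matches"] = r.matches,
    _["aligned_length"] = r.aln_len,
    _["q_start"] = r.q_start, _["q_end"] = r.q_end,
    _["s_start"] = r.s_start, _["s_end"] = r.s_end);
}
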