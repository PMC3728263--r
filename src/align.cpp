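#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (gap of length L costs
// gap_open + (L-1) * gap_extend; both negative). Full traceback; ties broken
// diagonal > up (gap in subject) > left (gap in query).
// [[Rcpp::export]]
List sw_align_cpp(std::string q, std::string s, double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int m = (int) q.size(), n = (int) s.size();
  const double NEG = -1e30;
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);  // gap in subject (up)
  std::vector<double> Fcur(n + 1, NEG);                     // gap in query (left)
  // traceback codes: 0 stop, 1 diag, 2 up, 3 left; E/F from: open(0)/extend(1)
  std::vector<unsigned char> tbH((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((size_t)(m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbF((size_t)(m + 1) * (n + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t) i * (n + 1) + j;
      double eo = Hprev[j] + gap_open, ee = Eprev[j] + gap_extend;
      Ecur[j] = (eo >= ee) ? eo : ee;
      tbE[idx] = (eo >= ee) ? 0 : 1;
      double fo = Hcur[j - 1] + gap_open, fe = Fcur[j - 1] + gap_extend;
      Fcur[j] = (fo >= fe) ? fo : fe;
      tbF[idx] = (fo >= fe) ? 0 : 1;
      double sc = (q[i - 1] == s[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + sc;
      double h = 0.0; unsigned char dir = 0;
      if (diag >= h) { h = diag; dir = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; dir = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; dir = 3; }
      Hcur[j] = h; tbH[idx] = dir;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E, 2 = F
  int qend = bi, send = bj, ncol = 0, nmatch = 0;
  int qstart = bi + 1, sstart = bj + 1;
  while (i > 0 && j > 0) {
    size_t idx = (size_t) i * (n + 1) + j;
    if (state == 0) {
      unsigned char d = tbH[idx];
      if (d == 0) break;
      if (d == 1) {
        ++ncol; if (q[i - 1] == s[j - 1]) ++nmatch;
        qstart = i; sstart = j; --i; --j;
      } else if (d == 2) { state = 1; }
      else { state = 2; }
    } else if (state == 1) {
      ++ncol; qstart = i;
      unsigned char e = tbE[idx];
      --i;
      state = (e == 0) ? 0 : 1;
    } else {
      ++ncol; sstart = j;
      unsigned char f = tbF[idx];
      --j;
      state = (f == 0) ? 0 : 2;
    }
  }
  double identity = (ncol > 0) ? 100.0 * nmatch / ncol : 0.0;
  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
                      _["sstart"] = sstart, _["send"] = send,
                      _["identity"] = identity, _["ncol"] = ncol);
}

// Score-only scan of a query against a long subject. Returns, for each subject
// position j, the maximum local alignment score of any alignment ending at j.
// [[Rcpp::export]]
NumericVector sw_scan_cpp(std::string q, std::string s, double match,
                          double mismatch, double gap_open, double gap_extend) {
  const int m = (int) q.size(), n = (int) s.size();
  const double NEG = -1e30;
  NumericVector colmax(n, 0.0);
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, NEG), Ecur(n + 1, NEG);
  std::vector<double> Fcur(n + 1, NEG);
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Fcur[0] = NEG;
    for (int j = 1; j <= n; ++j) {
      double e = std::max(Hprev[j] + gap_open, Eprev[j] + gap_extend);
      double f = std::max(Hcur[j - 1] + gap_open, Fcur[j - 1] + gap_extend);
      double sc = (q[i - 1] == s[j - 1]) ? match : mismatch;
      double h = Hprev[j - 1] + sc;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0.0) h = 0.0;
      Ecur[j] = e; Fcur[j] = f; Hcur[j] = h;
      if (h > colmax[j - 1]) colmax[j - 1] = h;
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  return colmax;
}

// Vectorized 3'-adaptor trimming. Removes, from the earliest position, either
// a full internal adaptor match or a terminal adaptor prefix of length >= 2;
// a 1-nt terminal overlap is left in place.
// [[Rcpp::export]]
CharacterVector trim_adaptor_cpp(CharacterVector reads, std::string adaptor) {
  const int alen = (int) adaptor.size();
  const int nr = reads.size();
  CharacterVector out(nr);
  for (int r = 0; r < nr; ++r) {
    if (reads[r] == NA_STRING) { out[r] = NA_STRING; continue; }
    std::string rd = as<std::string>(reads[r]);
    const int len = (int) rd.size();
    int cut = len;
    for (int i = 0; i < len; ++i) {
      int remaining = len - i;
      int k = std::min(remaining, alen);
      if (k < 2 && remaining < alen) break;
      bool hit = true;
      for (int t = 0; t < k; ++t) {
        if (rd[i + t] != adaptor[t]) { hit = false; break; }
      }
      // full internal match (remaining > alen) or terminal prefix >= 2
      if (hit && (remaining >= alen ? true : remaining >= 2)) { cut = i; break; }
    }
    out[r] = rd.substr(0, cut);
  }
  return out;
}
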