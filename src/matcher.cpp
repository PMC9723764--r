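#include <Rcpp.h>
using namespace Rcpp;

// Status codes shared with R: 0 assigned, 1 ambiguous, 2 unassigned,
// 3 too_short. flank_pos / middle_pos are 0-based positions within the
// barcode. Any character difference (including N) counts as a mismatch.
// [[Rcpp::export]]
List match_reads_cpp(CharacterVector reads, CharacterVector barcodes,
                     IntegerVector flank_pos, IntegerVector middle_pos,
                     int max_flank, int max_middle, int prefix_trim,
                     int barcode_length) {
  const int n = reads.size();
  const int m = barcodes.size();
  std::vector<std::string> bc(m);
  for (int j = 0; j < m; ++j) bc[j] = as<std::string>(barcodes[j]);

  IntegerVector status(n), idx(n), fmm(n), mmm(n);
  const int nf = flank_pos.size(), nm = middle_pos.size();

  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    const int len = LENGTH(STRING_ELT(reads, i));
    if (len < prefix_trim + barcode_length) {
      status[i] = 3;
      idx[i] = NA_INTEGER; fmm[i] = NA_INTEGER; mmm[i] = NA_INTEGER;
      continue;
    }
    const char *p = r + prefix_trim;
    int best = -1, best_total = INT_MAX, best_f = 0, best_m = 0;
    bool tie = false;
    for (int j = 0; j < m; ++j) {
      const char *b = bc[j].c_str();
      int f = 0;
      for (int k = 0; k < nf; ++k) {
        const int pos = flank_pos[k];
        if (p[pos] != b[pos] && ++f > max_flank) break;
      }
      if (f > max_flank) continue;
      int mm = 0;
      for (int k = 0; k < nm; ++k) {
        const int pos = middle_pos[k];
        if (p[pos] != b[pos] && ++mm > max_middle) break;
      }
      if (mm > max_middle) continue;
      const int tot = f + mm;
      if (tot < best_total) {
        best = j; best_total = tot; best_f = f; best_m = mm; tie = false;
      } else if (tot == best_total) {
        tie = true;
      }
    }
    if (best < 0) {
      status[i] = 2;
      idx[i] = NA_INTEGER; fmm[i] = NA_INTEGER; mmm[i] = NA_INTEGER;
    } else if (tie) {
      status[i] = 1;
      idx[i] = NA_INTEGER; fmm[i] = NA_INTEGER; mmm[i] = NA_INTEGER;
    } else {
      status[i] = 0;
      idx[i] = best + 1; fmm[i] = best_f; mmm[i] = best_m;
    }
  }
  return List::create(_["status"] = status, _["index"] = idx,
                      _["flank_mm"] = fmm, _["middle_mm"] = mmm);
}
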