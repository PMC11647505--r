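#include <Rcpp.h>
using namespace Rcpp;

static inline char upc(char c) { return (c >= 'a' && c <= 'z') ? c - 32 : c; }

static inline char comp(char c) {
  switch (upc(c)) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// base match: N never matches anything (each N costs one mismatch)
static inline bool base_eq(char a, char b) {
  char ua = upc(a), ub = upc(b);
  return ua == ub && ua != 'N';
}

// All minimum-mismatch ungapped end-to-end alignments of each insert against a
// set of reference sequences, both strands. Minus-strand hits are found by
// scanning the reverse complement of the insert along the forward reference;
// the reported interval is on the reference forward coordinates.
// Returns a list of integer/character vectors forming a hit table; indices
// are 1-based into `inserts` and `ref_seqs`.
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector inserts, CharacterVector ref_seqs,
                   int max_mismatches) {
  const int n_ins = inserts.size(), n_ref = ref_seqs.size();
  std::vector<std::string> refs(n_ref);
  for (int r = 0; r < n_ref; ++r) refs[r] = as<std::string>(ref_seqs[r]);

  std::vector<int> out_ins, out_ref, out_start, out_mm;
  std::vector<char> out_strand;

  for (int i = 0; i < n_ins; ++i) {
    std::string fwd = as<std::string>(inserts[i]);
    const int L = (int)fwd.size();
    if (L == 0) continue;
    std::string rev(L, 'N');
    for (int j = 0; j < L; ++j) rev[j] = comp(fwd[L - 1 - j]);

    int best = max_mismatches;
    std::vector<int> h_ref, h_start, h_mm;
    std::vector<char> h_strand;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string &q = strand == 0 ? fwd : rev;
      for (int r = 0; r < n_ref; ++r) {
        const std::string &ref = refs[r];
        const int RL = (int)ref.size();
        for (int s = 0; s + L <= RL; ++s) {
          int mm = 0;
          for (int j = 0; j < L; ++j) {
            if (!base_eq(q[j], ref[s + j])) {
              if (++mm > best) break;
            }
          }
          if (mm > best) continue;
          if (mm < best) {
            best = mm;
            h_ref.clear(); h_start.clear(); h_mm.clear(); h_strand.clear();
          }
          h_ref.push_back(r + 1);
          h_start.push_back(s);
          h_mm.push_back(mm);
          h_strand.push_back(strand == 0 ? '+' : '-');
        }
      }
    }
    for (size_t k = 0; k < h_ref.size(); ++k) {
      out_ins.push_back(i + 1);
      out_ref.push_back(h_ref[k]);
      out_start.push_back(h_start[k]);
      out_mm.push_back(h_mm[k]);
      out_strand.push_back(h_strand[k]);
    }
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  const int n = (int)out_ins.size();
  IntegerVector ins_idx(n), ref_idx(n), start(n), mm(n);
  CharacterVector strand(n);
  for (int k = 0; k < n; ++k) {
    ins_idx[k] = out_ins[k];
    ref_idx[k] = out_ref[k];
    start[k] = out_start[k];
    mm[k] = out_mm[k];
    strand[k] = std::string(1, out_strand[k]);
  }
  return List::create(_["insert_idx"] = ins_idx, _["ref_idx"] = ref_idx,
                      _["start"] = start, _["mismatches"] = mm,
                      _["strand"] = strand);
}

// Earliest 3' adapter occurrence per read. Internal occurrences must cover
// the full adapter; a truncated occurrence is allowed only where the read
// ends before the adapter does. Allowed mismatches: floor(max_error_rate *
// matched length). Returns the 0-based start of the match, or -1.
// [[Rcpp::export]]
IntegerVector cpp_find_adapter(CharacterVector seqs, std::string adapter,
                               double max_error_rate, int min_overlap) {
  const int n = seqs.size(), alen = (int)adapter.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int len = (int)s.size();
    int found = -1;
    for (int st = 0; st < len; ++st) {
      int ov = std::min(alen, len - st);
      if (ov < min_overlap) break;  // overlaps only shrink from here on
      int allowed = (int)std::floor(max_error_rate * ov);
      int mm = 0;
      for (int j = 0; j < ov; ++j) {
        if (!base_eq(s[st + j], adapter[j])) {
          if (++mm > allowed) break;
        }
      }
      if (mm <= allowed) { found = st; break; }
    }
    out[i] = found;
  }
  return out;
}
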