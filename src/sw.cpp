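#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap aligner, global in the query and local in the subject
// ("glocal"): every query base must be accounted for, while the alignment may
// start and end anywhere in the subject. Used to align generated haplotypes
// to the reference slice and reads to candidate haplotypes.
//
// Scoring: match/mismatch substitution scores; a gap of length k costs
// gap_open + k * gap_extend (both supplied as positive penalties).
//
// Tie-breaking is deterministic: diagonal (match state) is preferred over a
// subject-consuming gap (deletion), which is preferred over a
// query-consuming gap (insertion); the alignment end uses the smallest
// subject coordinate among maxima.
//
// Returns list(score, cigar, subject_start [1-based], subject_end).
// CIGAR ops: M consumes query+subject, I consumes query only (insertion
// relative to the subject), D consumes subject only (deletion).

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string subject,
                  double match = 2.0, double mismatch = -4.0,
                  double gap_open = 6.0, double gap_extend = 1.0) {
  const int m = (int)query.size();
  const int n = (int)subject.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  if (m == 0)
    return List::create(_["score"] = 0.0, _["cigar"] = "",
                        _["subject_start"] = 1, _["subject_end"] = 0);

  // state matrices: 0 = M (diagonal), 1 = Is (gap in query, consumes
  // subject), 2 = Iq (gap in subject, consumes query)
  std::vector<double> M((m + 1) * (n + 1), NEG);
  std::vector<double> Is((m + 1) * (n + 1), NEG);
  std::vector<double> Iq((m + 1) * (n + 1), NEG);
  // traceback: which state the max came from (0/1/2), per state
  std::vector<signed char> tbM((m + 1) * (n + 1), -1);
  std::vector<signed char> tbIs((m + 1) * (n + 1), -1);
  std::vector<signed char> tbIq((m + 1) * (n + 1), -1);

  const double go = gap_open + gap_extend;  // cost of opening a 1-base gap
  const double ge = gap_extend;

  #define AT(i, j) ((i) * (n + 1) + (j))

  for (int j = 0; j <= n; ++j) M[AT(0, j)] = 0.0;  // free start in subject
  for (int i = 1; i <= m; ++i) {
    Iq[AT(i, 0)] = -(gap_open + i * gap_extend);
    tbIq[AT(i, 0)] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M: diagonal move
      double s = (query[i - 1] == subject[j - 1]) ? match : mismatch;
      double bM = M[AT(i - 1, j - 1)];
      signed char fM = 0;
      if (Is[AT(i - 1, j - 1)] > bM) { bM = Is[AT(i - 1, j - 1)]; fM = 1; }
      if (Iq[AT(i - 1, j - 1)] > bM) { bM = Iq[AT(i - 1, j - 1)]; fM = 2; }
      M[AT(i, j)] = bM + s;
      tbM[AT(i, j)] = fM;
      // Is: consume subject (deletion in query coordinates)
      double bIs = M[AT(i, j - 1)] - go;
      signed char fIs = 0;
      if (Is[AT(i, j - 1)] - ge > bIs) { bIs = Is[AT(i, j - 1)] - ge; fIs = 1; }
      if (Iq[AT(i, j - 1)] - go > bIs) { bIs = Iq[AT(i, j - 1)] - go; fIs = 2; }
      Is[AT(i, j)] = bIs;
      tbIs[AT(i, j)] = fIs;
      // Iq: consume query (insertion relative to subject)
      double bIq = M[AT(i - 1, j)] - go;
      signed char fIq = 0;
      if (Is[AT(i - 1, j)] - go > bIq) { bIq = Is[AT(i - 1, j)] - go; fIq = 1; }
      if (Iq[AT(i - 1, j)] - ge > bIq) { bIq = Iq[AT(i - 1, j)] - ge; fIq = 2; }
      Iq[AT(i, j)] = bIq;
      tbIq[AT(i, j)] = fIq;
    }
  }

  // alignment must end having consumed the full query; trailing subject is
  // free, so take the best score in row m (state M or Iq; ending in Is would
  // waste a gap)
  double best = NEG;
  int bestJ = 0;
  signed char bestState = 0;
  for (int j = 0; j <= n; ++j) {
    if (M[AT(m, j)] > best) { best = M[AT(m, j)]; bestJ = j; bestState = 0; }
    if (Iq[AT(m, j)] > best) { best = Iq[AT(m, j)]; bestJ = j; bestState = 2; }
  }

  // traceback
  std::string ops;
  int i = m, j = bestJ;
  signed char st = bestState;
  while (i > 0) {
    signed char from;
    if (st == 0) {
      from = tbM[AT(i, j)];
      ops.push_back('M');
      --i; --j;
    } else if (st == 1) {
      from = tbIs[AT(i, j)];
      ops.push_back('D');
      --j;
    } else {
      from = tbIq[AT(i, j)];
      ops.push_back('I');
      --i;
    }
    st = from;
  }
  // drop leading deletions (start in subject is free); none should occur
  // because Is at row 0 is -inf, but guard anyway
  int subjStart = j + 1;  // 1-based first consumed subject base

  // run-length encode ops (reversed)
  std::string cigar;
  int k = (int)ops.size();
  int p = k - 1;
  while (p >= 0) {
    char op = ops[p];
    int len = 0;
    while (p >= 0 && ops[p] == op) { ++len; --p; }
    cigar += std::to_string(len);
    cigar.push_back(op);
  }

  return List::create(_["score"] = best, _["cigar"] = cigar,
                      _["subject_start"] = subjStart,
                      _["subject_end"] = bestJ);
}
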