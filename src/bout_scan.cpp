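#include <Rcpp.h>
using namespace Rcpp;

// Per-second hysteresis scan over a binary presence vector.
// A bout opens when a presence run reaches onset_min consecutive seconds
// (the bout starts at the first second of that run); once open, absences
// shorter than termination_gap are bridged, and an absence of at least
// termination_gap closes the bout one past its last present second.
// Sub-threshold runs before the first qualifying run are discarded.
// Returns an integer matrix with columns start, end (half-open, 0-based).
// [[Rcpp::export]]
IntegerMatrix scan_bouts(IntegerVector presence, int onset_min,
                         int termination_gap) {
  const int n = presence.size();
  std::vector<int> starts, ends;
  bool in_bout = false;
  int run_len = 0, run_start = 0, gap = 0;
  int bout_start = 0, last_present = -1;
  for (int t = 0; t < n; ++t) {
    if (presence[t] != 0) {
      if (run_len == 0) run_start = t;
      ++run_len;
      gap = 0;
      last_present = t;
      if (!in_bout && run_len >= onset_min) {
        in_bout = true;
        bout_start = run_start;
      }
    } else {
      run_len = 0;
      ++gap;
      if (in_bout && gap >= termination_gap) {
        starts.push_back(bout_start);
        ends.push_back(last_present + 1);
        in_bout = false;
      }
    }
  }
  if (in_bout) {  // truncated at the day boundary
    starts.push_back(bout_start);
    ends.push_back(last_present + 1);
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t i = 0; i < starts.size(); ++i) {
    out(i, 0) = starts[i];
    out(i, 1) = ends[i];
  }
  colnames(out) = CharacterVector::create("start_s", "end_s");
  return out;
}
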