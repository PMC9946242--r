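#include <Rcpp.h>
using namespace Rcpp;

// Monte-Carlo absorbed random walk on a raster resistor network.
//
// nbr:    n_cells x k matrix of 0-based neighbour cell indices (-1 = none)
// cum:    n_cells x k matrix of cumulative transition probabilities per cell
// start:  0-based start cells (walkers drawn uniformly among them)
// absorb: logical absorption flags per cell (the ground strip)
//
// Tracks two things per walk:
//  * gross visits per cell (every occupancy, start and absorption included)
//  * signed directed traversal counts per (cell, neighbour-slot); the net
//    count across walkers estimates the edge current of the equivalent
//    circuit (expected net crossings of an edge equal the current on it),
//    which is the "probability of use" sense in which current density
//    describes a random walk.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export(name = ".walk_visits_cpp")]]
List walk_visits_cpp(IntegerMatrix nbr, NumericMatrix cum,
                     IntegerVector start, LogicalVector absorb,
                     int n_walkers, int step_cap) {
  int n_cells = nbr.nrow(), k = nbr.ncol(), n_start = start.size();
  std::vector<double> visits(n_cells, 0.0);
  std::vector<double> starts(n_cells, 0.0), ends(n_cells, 0.0);
  NumericMatrix flow(n_cells, k);  // directed traversal counts
  int absorbed = 0, discarded = 0;
  RNGScope scope;
  for (int w = 0; w < n_walkers; ++w) {
    int cell = start[(int)(unif_rand() * n_start) % n_start];
    visits[cell] += 1.0;
    starts[cell] += 1.0;
    bool done = absorb[cell];
    if (done) { ends[cell] += 1.0; ++absorbed; }
    int steps = 0;
    while (!done && steps < step_cap) {
      double u = unif_rand();
      int slot = k - 1;
      for (int j = 0; j < k; ++j) {
        if (u <= cum(cell, j)) { slot = j; break; }
      }
      int next = nbr(cell, slot);
      if (next < 0) next = cell;  // numerical guard, never expected
      else flow(cell, slot) += 1.0;
      cell = next;
      visits[cell] += 1.0;
      ++steps;
      if (absorb[cell]) { done = true; ++absorbed; ends[cell] += 1.0; }
    }
    if (!done) ++discarded;
  }
  return List::create(_["visits"] = NumericVector(visits.begin(), visits.end()),
                      _["flow"] = flow,
                      _["starts"] = NumericVector(starts.begin(), starts.end()),
                      _["ends"] = NumericVector(ends.begin(), ends.end()),
                      _["absorbed"] = absorbed, _["discarded"] = discarded);
}
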