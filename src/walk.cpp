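#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Lattice random-walk binding engine.
//
// Geometry: nx x ny x nz lattice (0-based coordinates), channels immobilized
// on the z = 0 face. Free ligates take 6-neighbour (von Neumann) steps with
// myopic reflecting boundaries: off-lattice moves get zero weight and the
// weights are renormalized; if every move is blocked the ligate stays.
// Moving onto a channel site whose channel is unbound has its weight
// multiplied by `attraction`. A free ligate standing on an unbound channel
// site binds with probability p_bind at the start of its update (and
// otherwise moves on); a bound ligate unbinds with probability p_unbind and
// is displaced to a uniformly chosen admissible neighbour. A channel binds
// at most one ligate. Ligates are updated sequentially in index order; all
// randomness comes from R's RNG so set.seed() governs the run.
//
// exclusion = false (default model): ligates are volumeless; any number may
//   share a site; a bound channel site is passable (weight 1, no
//   attraction).
// exclusion = true (strict variant): a channel site holds at most one
//   ligate, standing or bound; occupied channel sites are impassable.
//
// [[Rcpp::export]]
List walk_engine_cpp(IntegerMatrix ligate0, IntegerVector bound0,
                     IntegerMatrix channels,
                     int nx, int ny, int nz, int n_steps,
                     double p_bind, double p_unbind, double attraction,
                     bool exclusion) {
  int n = ligate0.nrow();
  int k = channels.nrow();
  std::vector<int> lx(n), ly(n), lz(n);
  std::vector<int> bound(n);              // channel index (0-based) or -1
  for (int i = 0; i < n; ++i) {
    lx[i] = ligate0(i, 0); ly[i] = ligate0(i, 1); lz[i] = ligate0(i, 2);
    bound[i] = bound0[i];
  }
  std::vector<int> chan_at((size_t)nx * ny, -1);
  std::vector<int> chan_bound(k, 0);      // channel has a bound ligate
  std::vector<int> occupant(k, -1);       // exclusion mode: standing/bound
  for (int c = 0; c < k; ++c)
    chan_at[channels(c, 0) + (size_t)nx * channels(c, 1)] = c;
  for (int i = 0; i < n; ++i) {
    if (bound[i] >= 0) {
      chan_bound[bound[i]] = 1;
      occupant[bound[i]] = i;
    } else if (exclusion && lz[i] == 0) {
      int c = chan_at[lx[i] + (size_t)nx * ly[i]];
      if (c >= 0) occupant[c] = i;
    }
  }
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  IntegerVector bound_trace(n_steps);
  int n_bound = 0;
  for (int c = 0; c < k; ++c) if (chan_bound[c]) ++n_bound;

  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) {
      int cur_chan = (lz[i] == 0) ? chan_at[lx[i] + (size_t)nx * ly[i]] : -1;
      if (bound[i] >= 0) {
        if (unif_rand() < p_unbind) {
          int cand[6], ncand = 0;
          for (int m = 0; m < 6; ++m) {
            int xx = lx[i] + dx[m], yy = ly[i] + dy[m], zzp = lz[i] + dz[m];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zzp < 0 ||
                zzp >= nz)
              continue;
            if (exclusion && zzp == 0) {
              int c2 = chan_at[xx + (size_t)nx * yy];
              if (c2 >= 0 && occupant[c2] >= 0) continue;
            }
            cand[ncand++] = m;
          }
          chan_bound[bound[i]] = 0;
          occupant[bound[i]] = -1;
          bound[i] = -1;
          --n_bound;
          if (ncand > 0) {
            int m = cand[(int)(unif_rand() * ncand) % ncand];
            lx[i] += dx[m]; ly[i] += dy[m]; lz[i] += dz[m];
            if (exclusion && lz[i] == 0) {
              int c2 = chan_at[lx[i] + (size_t)nx * ly[i]];
              if (c2 >= 0) occupant[c2] = i;
            }
          } else if (exclusion) {
            occupant[cur_chan] = i;  // stays, standing unbound on its site
          }
        }
        continue;
      }
      // free ligate standing on an unbound channel site: binding attempt
      if (cur_chan >= 0 && !chan_bound[cur_chan] &&
          (!exclusion || occupant[cur_chan] == i) &&
          unif_rand() < p_bind) {
        bound[i] = cur_chan;
        chan_bound[cur_chan] = 1;
        occupant[cur_chan] = i;
        ++n_bound;
        continue;
      }
      // move with weights
      double w[6], tot = 0.0;
      for (int m = 0; m < 6; ++m) {
        int xx = lx[i] + dx[m], yy = ly[i] + dy[m], zzp = lz[i] + dz[m];
        double wm = 0.0;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zzp >= 0 &&
            zzp < nz) {
          wm = 1.0;
          if (zzp == 0) {
            int c2 = chan_at[xx + (size_t)nx * yy];
            if (c2 >= 0) {
              if (exclusion) {
                wm = (occupant[c2] >= 0) ? 0.0 : attraction;
              } else {
                wm = chan_bound[c2] ? 1.0 : attraction;
              }
            }
          }
        }
        w[m] = wm;
        tot += wm;
      }
      if (tot <= 0.0) continue;  // fully blocked: stay
      double u = unif_rand() * tot, acc = 0.0;
      int pick = 5;
      for (int m = 0; m < 6; ++m) {
        acc += w[m];
        if (u <= acc) { pick = m; break; }
      }
      if (w[pick] == 0.0) continue;
      if (exclusion && cur_chan >= 0 && occupant[cur_chan] == i)
        occupant[cur_chan] = -1;
      lx[i] += dx[pick]; ly[i] += dy[pick]; lz[i] += dz[pick];
      if (exclusion && lz[i] == 0) {
        int c2 = chan_at[lx[i] + (size_t)nx * ly[i]];
        if (c2 >= 0) occupant[c2] = i;
      }
    }
    bound_trace[t] = n_bound;
  }

  IntegerMatrix pos(n, 3);
  IntegerVector bnd(n);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = lx[i]; pos(i, 1) = ly[i]; pos(i, 2) = lz[i];
    bnd[i] = bound[i];
  }
  return List::create(_["bound_trace"] = bound_trace,
                      _["positions"] = pos,
                      _["bound_channel"] = bnd);
}
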