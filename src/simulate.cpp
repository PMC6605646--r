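// Agent-based stop-and-go simulator for spiderlings in a circular arena,
// optionally partitioned by zero-thickness radial inner walls with a central
// opening.  Each agent alternates between wall-following (outer wall or an
// inner wall), diffusive movement in the open center, and stopped bouts whose
// leaving hazard is delta + alpha/(beta + t) with alpha scaled by aggregate
// size, shifted at the maturational day, and optionally modulated by social
// rules (stopping near stopped conspecifics, moving after collisions).
//
// Each agent owns an independent RNG stream seeded from (master seed, run,
// agent id), so removing conspecifics or toggling social rules leaves the
// remaining agents' draw sequences untouched.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

constexpr double TWO_PI = 6.283185307179586;

enum Mode { EDGE_OUTER = 0, EDGE_WALL = 1, CENTER = 2, STOPPED = 3 };

struct Agent {
  int mode = CENTER;
  double x = 0, y = 0;
  // edge_outer
  double theta = 0;
  int dir = 1;
  // edge_wall
  int wall = 0;
  int side = 1;
  double rpos = 0;
  int wdir = -1;
  // center
  double heading = 0;
  // stopped
  double t_stop = 0;
  int resume_mode = CENTER;
  bool in_contact = false;
  bool collided = false;
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  std::normal_distribution<double> norm{0.0, 1.0};
  double u() { return unif(eng); }
  double z() { return norm(eng); }
};

struct Geometry {
  double R = 40, r0 = 10, wall_zone = 5;
  int n_walls = 0;
  std::vector<double> wall_angle, wcos, wsin;
};

inline double wrap_angle(double a) {
  a = std::fmod(a, TWO_PI);
  if (a < 0) a += TWO_PI;
  return a;
}

// signed angular difference b - a wrapped to (-pi, pi]
inline double ang_diff(double a, double b) {
  double d = std::fmod(b - a + 3 * M_PI, TWO_PI);
  return d - M_PI;
}

// does the motion segment (x,y) -> (nx,ny) cross inner wall w?
inline bool crosses_wall(const Geometry& g, int w, double x, double y,
                         double nx, double ny, double& rcross) {
  // wall w lies along direction (wcos, wsin) for radii [r0, R]
  double c = g.wcos[w], s = g.wsin[w];
  // side coordinates (perpendicular to the wall)
  double p1 = -s * x + c * y;
  double p2 = -s * nx + c * ny;
  if ((p1 > 0) == (p2 > 0)) return false;   // same side, no crossing
  double t = p1 / (p1 - p2);                // crossing parameter
  double cx = x + t * (nx - x), cy = y + t * (ny - y);
  double r = c * cx + s * cy;               // radial coordinate along wall
  if (r < g.r0 || r > g.R) return false;    // passes through the opening/past wall
  rcross = r;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List sim_abm_cpp(List arena, List pars, int n_agents, double dt,
                 double total_s, double snapshot_every, bool social,
                 bool shift, int master_seed, int run_id,
                 NumericMatrix init_xy) {
  Geometry g;
  g.R = as<double>(arena["radius"]);
  g.r0 = as<double>(arena["opening_radius"]);
  g.wall_zone = as<double>(arena["wall_zone_width"]);
  g.n_walls = as<int>(arena["n_compartments"]);
  if (g.n_walls > 0) {
    NumericVector wa = arena["wall_angles"];
    for (double a : wa) {
      g.wall_angle.push_back(a);
      g.wcos.push_back(std::cos(a));
      g.wsin.push_back(std::sin(a));
    }
  }

  const double V = as<double>(pars["V"]);
  const double tau_p = as<double>(pars["tau_p"]);
  const double l_star = as<double>(pars["l_star"]);
  const double tau_stop_c = as<double>(pars["tau_stop_c"]);
  const double P_w = as<double>(pars["P_w"]);
  const double P_c = as<double>(pars["P_c"]);
  NumericVector stop_given_N = pars["stop_given_N"];
  NumericVector move_collision = pars["move_after_collision_given_N"];
  NumericVector edge_event = pars["edge_event_probs"];  // exit, uturn, stop
  const double alpha_single = as<double>(pars["alpha_single"]);
  const double alpha_pair_agg = as<double>(pars["alpha_pair_aggregate"]);
  const double beta = as<double>(pars["beta"]);
  const double delta = as<double>(pars["delta"]);
  const double shift_day = as<double>(pars["shift_day"]);
  const double shift_factor = as<double>(pars["shift_factor"]);
  const double contact_radius = as<double>(pars["contact_radius"]);
  const double collision_radius = as<double>(pars["collision_radius"]);
  const double aggregate_radius = as<double>(pars["aggregate_radius"]);

  const double step_len = V * dt;
  if (step_len >= l_star)
    stop("V * dt must be smaller than l_star for the correlated walk");
  const double sigma = std::sqrt(-2.0 * std::log(1.0 - step_len / l_star));
  const double p_edge_event = std::min(1.0, dt / tau_p);
  const double p_center_stop = std::min(1.0, dt / tau_stop_c);

  std::vector<Agent> ag(n_agents);
  for (int i = 0; i < n_agents; ++i) {
    std::seed_seq seq{master_seed, run_id, i};
    ag[i].eng.seed(seq);
    ag[i].x = init_xy(i, 0);
    ag[i].y = init_xy(i, 1);
    ag[i].mode = CENTER;
    ag[i].heading = ag[i].u() * TWO_PI;
  }

  const long n_steps = (long)std::llround(total_s / dt);
  const long every = std::max(1L, (long)std::llround(snapshot_every / dt));
  const long n_snap = n_steps / every + 1;

  NumericVector out_t(n_snap * n_agents);
  IntegerVector out_id(n_snap * n_agents);
  NumericVector out_x(n_snap * n_agents), out_y(n_snap * n_agents);
  IntegerVector out_mode(n_snap * n_agents);
  long snap_row = 0;

  std::vector<double> px(n_agents), py(n_agents);
  std::vector<int> pmode(n_agents), agg_size(n_agents, 1);
  std::vector<int> cluster(n_agents);

  auto record = [&](double t) {
    for (int i = 0; i < n_agents; ++i) {
      out_t[snap_row] = t;
      out_id[snap_row] = i + 1;
      out_x[snap_row] = ag[i].x;
      out_y[snap_row] = ag[i].y;
      out_mode[snap_row] = ag[i].mode;
      ++snap_row;
    }
  };
  record(0.0);

  for (long step = 0; step < n_steps; ++step) {
    const double t = step * dt;
    const double day = std::floor(t / 86400.0) + 1.0;

    for (int i = 0; i < n_agents; ++i) {
      px[i] = ag[i].x;
      py[i] = ag[i].y;
      pmode[i] = ag[i].mode;
    }

    // single-linkage clusters of stopped agents within aggregate_radius
    for (int i = 0; i < n_agents; ++i) cluster[i] = i;
    if (social) {
      for (int i = 0; i < n_agents; ++i) {
        if (pmode[i] != STOPPED) continue;
        for (int j = i + 1; j < n_agents; ++j) {
          if (pmode[j] != STOPPED) continue;
          double dx = px[i] - px[j], dy = py[i] - py[j];
          if (dx * dx + dy * dy <= aggregate_radius * aggregate_radius) {
            int ci = cluster[i], cj = cluster[j];
            if (ci != cj)
              for (int k = 0; k < n_agents; ++k)
                if (cluster[k] == cj) cluster[k] = ci;
          }
        }
      }
    }
    for (int i = 0; i < n_agents; ++i) agg_size[i] = 0;
    for (int i = 0; i < n_agents; ++i)
      if (pmode[i] == STOPPED) ++agg_size[cluster[i]];
    for (int i = 0; i < n_agents; ++i)
      if (pmode[i] == STOPPED && cluster[i] != i)
        agg_size[i] = agg_size[cluster[i]];
    for (int i = 0; i < n_agents; ++i)
      if (agg_size[i] == 0) agg_size[i] = 1;

    for (int i = 0; i < n_agents; ++i) {
      Agent& a = ag[i];

      if (a.mode == STOPPED) {
        bool leaves = false;
        // collision: one draw per contact onset by a moving conspecific
        if (social) {
          bool hit = false;
          for (int j = 0; j < n_agents; ++j) {
            if (j == i || pmode[j] == STOPPED) continue;
            double dx = px[i] - px[j], dy = py[i] - py[j];
            if (dx * dx + dy * dy <= collision_radius * collision_radius) {
              hit = true;
              break;
            }
          }
          if (hit && !a.collided) {
            int idx = std::min(agg_size[i], 3) - 1;
            if (a.u() < move_collision[idx]) leaves = true;
          }
          a.collided = hit;
        }
        if (!leaves) {
          double alpha;
          int N = social ? agg_size[i] : 1;
          if (N <= 1) alpha = alpha_single;
          else if (N == 2) alpha = alpha_pair_agg / 2.0;
          else if (N == 3) alpha = alpha_single / 5.0;
          else alpha = alpha_single / 10.0;
          if (shift && day >= shift_day) alpha *= shift_factor;
          double p = (delta + alpha / (beta + a.t_stop)) * dt;
          if (p > 1) p = 1;
          if (a.u() < p) leaves = true;
          else a.t_stop += dt;
        }
        if (leaves) {
          a.mode = a.resume_mode;
          a.t_stop = 0;
          a.collided = false;
          // still within contact range of its former aggregate: require a
          // genuine departure before a new social stop draw can fire
          a.in_contact = true;
          if (a.mode == EDGE_OUTER) {
            a.theta = std::atan2(a.y, a.x);
            a.dir = (a.u() < 0.5) ? 1 : -1;
          } else if (a.mode == EDGE_WALL) {
            a.wdir = (a.u() < 0.5) ? 1 : -1;
          } else {
            a.heading = a.u() * TWO_PI;
          }
        }
        continue;
      }

      // --- moving agents -------------------------------------------------
      // social stopping: one draw when first coming within contact range of
      // stopped conspecifics
      if (social) {
        int N = 0;
        for (int j = 0; j < n_agents; ++j) {
          if (j == i || pmode[j] != STOPPED) continue;
          double dx = px[i] - px[j], dy = py[i] - py[j];
          if (dx * dx + dy * dy <= contact_radius * contact_radius) ++N;
        }
        if (N > 0 && !a.in_contact) {
          int idx = std::min(N, 3) - 1;
          if (a.u() < stop_given_N[idx]) {
            a.resume_mode = a.mode;
            a.mode = STOPPED;
            a.t_stop = 0;
            a.in_contact = true;
            continue;
          }
        }
        a.in_contact = (N > 0);
      }

      if (a.mode == EDGE_OUTER) {
        if (a.u() < p_edge_event) {
          double u = a.u();
          if (u < edge_event[0]) {  // exit toward the center
            a.mode = CENTER;
            a.heading = wrap_angle(a.theta + M_PI + (a.u() - 0.5) * M_PI / 1.5);
          } else if (u < edge_event[0] + edge_event[1]) {  // U-turn
            a.dir = -a.dir;
          } else {  // spontaneous stop at the edge
            a.resume_mode = EDGE_OUTER;
            a.mode = STOPPED;
            a.t_stop = 0;
          }
          continue;
        }
        double dtheta = a.dir * step_len / g.R;
        double new_theta = a.theta + dtheta;
        // corner check: does the angular move cross a wall angle?
        bool at_corner = false;
        int wcorner = -1;
        if (g.n_walls > 0) {
          for (int w = 0; w < g.n_walls; ++w) {
            double d0 = ang_diff(a.theta, g.wall_angle[w]);
            if (a.dir > 0 ? (d0 > 1e-12 && d0 <= dtheta)
                          : (d0 < -1e-12 && d0 >= dtheta)) {
              at_corner = true;
              wcorner = w;
              break;
            }
          }
        }
        if (at_corner) {
          a.theta = g.wall_angle[wcorner];
          a.x = g.R * std::cos(a.theta) * 0.999;
          a.y = g.R * std::sin(a.theta) * 0.999;
          int approach_side = (a.dir > 0) ? -1 : 1;  // side the agent came from
          if (a.u() < P_c) {  // stop in the corner
            a.resume_mode = EDGE_WALL;
            a.wall = wcorner;
            a.side = approach_side;
            a.rpos = g.R * 0.999;
            a.mode = STOPPED;
            a.t_stop = 0;
          } else {  // turn onto the inner wall, heading inward
            a.mode = EDGE_WALL;
            a.wall = wcorner;
            a.side = approach_side;
            a.rpos = g.R * 0.999;
            a.wdir = -1;
          }
        } else {
          a.theta = wrap_angle(new_theta);
          a.x = g.R * std::cos(a.theta) * 0.999;
          a.y = g.R * std::sin(a.theta) * 0.999;
        }
        continue;
      }

      if (a.mode == EDGE_WALL) {
        if (a.u() < p_edge_event) {
          double u = a.u();
          double normal = g.wall_angle[a.wall] + a.side * M_PI / 2;
          if (u < edge_event[0]) {  // leave the wall
            a.mode = CENTER;
            a.heading = wrap_angle(normal + (a.u() - 0.5) * M_PI / 1.5);
          } else if (u < edge_event[0] + edge_event[1]) {
            a.wdir = -a.wdir;
          } else {
            a.resume_mode = EDGE_WALL;
            a.mode = STOPPED;
            a.t_stop = 0;
          }
          continue;
        }
        a.rpos += a.wdir * step_len;
        if (a.rpos <= g.r0) {  // reached the wall tip at the central opening
          a.rpos = g.r0;
          double c = g.wcos[a.wall], s = g.wsin[a.wall];
          a.x = c * g.r0 - a.side * s * 0.2;
          a.y = s * g.r0 + a.side * c * 0.2;
          if (a.u() < P_w) {  // stop at the inner-wall end
            a.resume_mode = CENTER;
            a.mode = STOPPED;
            a.t_stop = 0;
          } else {  // continue into the central opening
            a.mode = CENTER;
            a.heading = wrap_angle(g.wall_angle[a.wall] + M_PI +
                                   (a.u() - 0.5) * M_PI / 1.5);
          }
        } else if (a.rpos >= g.R * 0.999) {  // back at the outer corner
          a.rpos = g.R * 0.999;
          double c = g.wcos[a.wall], s = g.wsin[a.wall];
          a.x = c * a.rpos - a.side * s * 0.2;
          a.y = s * a.rpos + a.side * c * 0.2;
          if (a.u() < P_c) {
            a.resume_mode = EDGE_WALL;
            a.mode = STOPPED;
            a.t_stop = 0;
          } else {  // move off along the outer wall on this side
            a.mode = EDGE_OUTER;
            a.theta = wrap_angle(g.wall_angle[a.wall] + a.side * 0.02);
            a.dir = a.side;
          }
        } else {
          double c = g.wcos[a.wall], s = g.wsin[a.wall];
          a.x = c * a.rpos - a.side * s * 0.2;
          a.y = s * a.rpos + a.side * c * 0.2;
        }
        continue;
      }

      // CENTER: correlated random walk
      if (a.u() < p_center_stop) {
        a.resume_mode = CENTER;
        a.mode = STOPPED;
        a.t_stop = 0;
        continue;
      }
      a.heading = wrap_angle(a.heading + sigma * a.z());
      double nx = a.x + step_len * std::cos(a.heading);
      double ny = a.y + step_len * std::sin(a.heading);
      // inner wall collision: attach to the wall at the crossing point
      bool attached = false;
      if (g.n_walls > 0) {
        for (int w = 0; w < g.n_walls; ++w) {
          double rc;
          if (crosses_wall(g, w, a.x, a.y, nx, ny, rc)) {
            double pside = -g.wsin[w] * a.x + g.wcos[w] * a.y;
            a.mode = EDGE_WALL;
            a.wall = w;
            a.side = (pside >= 0) ? 1 : -1;
            a.rpos = std::min(std::max(rc, g.r0), g.R * 0.999);
            double radial_vel = g.wcos[w] * (nx - a.x) + g.wsin[w] * (ny - a.y);
            a.wdir = radial_vel > 0 ? 1 : (radial_vel < 0 ? -1 : (a.u() < 0.5 ? 1 : -1));
            double c = g.wcos[w], s = g.wsin[w];
            a.x = c * a.rpos - a.side * s * 0.2;
            a.y = s * a.rpos + a.side * c * 0.2;
            attached = true;
            break;
          }
        }
      }
      if (attached) continue;
      double nr = std::sqrt(nx * nx + ny * ny);
      double radial_out = (nx * std::cos(a.heading) + ny * std::sin(a.heading));
      if (nr >= g.R - g.wall_zone && radial_out > 0) {
        // entered the outer wall zone moving outward: start wall-following
        a.mode = EDGE_OUTER;
        a.theta = std::atan2(ny, nx);
        double cross = a.x * std::sin(a.heading) - a.y * std::cos(a.heading);
        a.dir = cross >= 0 ? 1 : -1;
        a.x = g.R * std::cos(a.theta) * 0.999;
        a.y = g.R * std::sin(a.theta) * 0.999;
      } else {
        if (nr >= g.R) {  // numerical safety: reflect inward
          nx *= (g.R - 0.5) / nr;
          ny *= (g.R - 0.5) / nr;
          a.heading = wrap_angle(a.heading + M_PI);
        }
        a.x = nx;
        a.y = ny;
      }
    }

    if ((step + 1) % every == 0) record((step + 1) * dt);
  }

  return List::create(
    _["t_s"] = out_t, _["id"] = out_id, _["x_mm"] = out_x,
    _["y_mm"] = out_y, _["mode"] = out_mode);
}
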