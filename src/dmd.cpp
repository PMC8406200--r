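// Event-driven (discrete) molecular dynamics over stepwise pair potentials.
//
// Beads interact through three pair classes:
//   bond    - hard window [bondLow, bondHigh] * native length
//   contact - square well: hard core at wellLow*d0, attractive well of depth
//             eps out to wellHigh*d0
//   other   - hardcore repulsion at a fixed diameter
// Between events motion is ballistic; at an event the radial component of the
// relative velocity is updated by exact energy/momentum conservation (equal
// unit masses, reduced mass 1/2). An Andersen-style thermostat resamples a
// random bead's velocity at a Poisson rate. All randomness comes from an
// internal 64-bit generator seeded explicitly, so a fixed seed gives a
// bit-identical trajectory.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>

using namespace Rcpp;

namespace {

const uint8_t PT_NONE = 0, PT_BOND = 1, PT_CONTACT = 2;
// event kinds
const uint8_t EV_HARD = 0, EV_WELL_EXIT = 2, EV_WELL_ENTER = 3;

struct Event {
  double t;
  int i, j;            // j == -1 marks a thermostat event (never queued)
  uint32_t ci, cj;     // collision counters at prediction time
  uint8_t kind;
};
struct EventCmp {
  bool operator()(const Event &a, const Event &b) const { return a.t > b.t; }
};

struct Rng {
  std::mt19937_64 eng;
  bool haveSpare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() {  // in (0,1)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {  // Box-Muller, implementation-pinned for determinism
    if (haveSpare) { haveSpare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    haveSpare = true;
    return r * std::cos(th);
  }
};

struct Sim {
  int N;
  std::vector<double> x, v;          // 3N each
  std::vector<uint8_t> ptype;        // N*N dense pair table
  std::vector<double> rin2, rout2;   // squared wall radii
  std::vector<uint8_t> inWell;       // contact-pair well occupancy
  std::vector<uint32_t> counter;     // per-bead collision counters
  double eps, U;
  double tcur = 0.0;
  std::priority_queue<Event, std::vector<Event>, EventCmp> queue;

  inline size_t idx(int i, int j) const { return (size_t)i * N + j; }

  double dist2(int i, int j) const {
    double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
           dz = x[3 * j + 2] - x[3 * i + 2];
    return dx * dx + dy * dy + dz * dz;
  }

  // Predict next event for pair (i, j) and push it onto the queue.
  void predict(int i, int j) {
    size_t p = idx(i, j);
    uint8_t ty = ptype[p];
    double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
           dz = x[3 * j + 2] - x[3 * i + 2];
    double dvx = v[3 * j] - v[3 * i], dvy = v[3 * j + 1] - v[3 * i + 1],
           dvz = v[3 * j + 2] - v[3 * i + 2];
    double a = dvx * dvx + dvy * dvy + dvz * dvz;
    if (a <= 0.0) return;
    double b = dx * dvx + dy * dvy + dz * dvz;
    double r2 = dx * dx + dy * dy + dz * dz;
    const double TMIN = 1e-12;

    double bestT = R_PosInf;
    uint8_t bestK = EV_HARD;

    auto considerInner = [&](double R2, uint8_t kind) {
      // approach to an inner hard surface from outside
      if (b >= 0.0) return;
      double c = r2 - R2;
      double disc = b * b - a * c;
      if (disc <= 0.0) return;
      double t = c <= 0.0 ? TMIN : (-b - std::sqrt(disc)) / a;
      if (t > TMIN && t < bestT) { bestT = t; bestK = kind; }
      else if (c <= 0.0 && TMIN < bestT) { bestT = TMIN; bestK = kind; }
    };
    auto considerOuterFromInside = [&](double R2, uint8_t kind) {
      double c = r2 - R2;
      if (c >= 0.0) {  // marginally outside by round-off
        if (b > 0.0) { if (TMIN < bestT) { bestT = TMIN; bestK = kind; } }
        return;
      }
      double disc = b * b - a * c;  // > 0 since c < 0
      double t = (-b + std::sqrt(disc)) / a;
      if (t > TMIN && t < bestT) { bestT = t; bestK = kind; }
    };

    if (ty == PT_BOND) {
      considerInner(rin2[p], EV_HARD);
      considerOuterFromInside(rout2[p], EV_HARD);
    } else if (ty == PT_CONTACT) {
      if (inWell[p]) {
        considerInner(rin2[p], EV_HARD);
        considerOuterFromInside(rout2[p], EV_WELL_EXIT);
      } else {
        considerInner(rout2[p], EV_WELL_ENTER);
      }
    } else {
      considerInner(rin2[p], EV_HARD);
    }

    if (R_FINITE(bestT)) {
      Event e;
      e.t = tcur + bestT;
      e.i = i; e.j = j;
      e.ci = counter[i]; e.cj = counter[j];
      e.kind = bestK;
      queue.push(e);
    }
  }

  void predictAllFor(int i) {
    for (int k = 0; k < N; ++k)
      if (k != i) predict(std::min(i, k), std::max(i, k));
  }

  void advanceTo(double t) {
    double dt = t - tcur;
    if (dt > 0.0) {
      for (int i = 0; i < 3 * N; ++i) x[i] += v[i] * dt;
      tcur = t;
    }
  }

  // Execute the pair interaction of a valid popped event.
  void collide(const Event &e) {
    int i = e.i, j = e.j;
    size_t p = idx(i, j);
    double dx = x[3 * j] - x[3 * i], dy = x[3 * j + 1] - x[3 * i + 1],
           dz = x[3 * j + 2] - x[3 * i + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double nx = dx / r, ny = dy / r, nz = dz / r;
    double vr = (v[3 * j] - v[3 * i]) * nx + (v[3 * j + 1] - v[3 * i + 1]) * ny +
                (v[3 * j + 2] - v[3 * i + 2]) * nz;
    double vrNew;
    if (e.kind == EV_HARD) {
      vrNew = -vr;
    } else if (e.kind == EV_WELL_EXIT) {
      // escape needs (1/2) mu vr^2 >= eps with mu = 1/2, i.e. vr^2 >= 4 eps
      if (vr > 0.0 && vr * vr >= 4.0 * eps) {
        vrNew = std::sqrt(vr * vr - 4.0 * eps);
        inWell[p] = 0;
        U += eps;
      } else {
        vrNew = -vr;
      }
    } else {  // EV_WELL_ENTER
      vrNew = -std::sqrt(vr * vr + 4.0 * eps);
      inWell[p] = 1;
      U -= eps;
    }
    double half = 0.5 * (vrNew - vr);
    v[3 * j] += half * nx;     v[3 * i] -= half * nx;
    v[3 * j + 1] += half * ny; v[3 * i + 1] -= half * ny;
    v[3 * j + 2] += half * nz; v[3 * i + 2] -= half * nz;
    ++counter[i];
    ++counter[j];
  }

  double kinetic() const {
    double k = 0.0;
    for (int i = 0; i < 3 * N; ++i) k += v[i] * v[i];
    return 0.5 * k;
  }
};

}  // namespace

// [[Rcpp::export(name = ".dmd_run")]]
List dmd_run(NumericMatrix coords, IntegerMatrix bonds, NumericVector bondLen,
             IntegerMatrix contacts, NumericVector contactD0, double eps,
             double wellLow, double wellHigh, double hardcore, double bondLow,
             double bondHigh, double temperature, double thermostatRate,
             double nSteps, int snapshotEvery, int seed,
             Nullable<NumericMatrix> initVel = R_NilValue) {
  int N = coords.nrow();
  if (N < 2) stop("need at least 2 beads");
  Sim s;
  s.N = N;
  s.eps = eps;
  s.U = 0.0;
  s.x.resize(3 * N);
  s.v.assign(3 * N, 0.0);
  s.counter.assign(N, 0);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) s.x[3 * i + d] = coords(i, d);

  // dense pair tables (upper triangle used, i < j)
  s.ptype.assign((size_t)N * N, PT_NONE);
  s.rin2.assign((size_t)N * N, hardcore * hardcore);
  s.rout2.assign((size_t)N * N, 0.0);
  s.inWell.assign((size_t)N * N, 0);
  for (int k = 0; k < bonds.nrow(); ++k) {
    int i = bonds(k, 0) - 1, j = bonds(k, 1) - 1;
    if (i > j) std::swap(i, j);
    size_t p = s.idx(i, j);
    s.ptype[p] = PT_BOND;
    double lo = bondLow * bondLen[k], hi = bondHigh * bondLen[k];
    s.rin2[p] = lo * lo;
    s.rout2[p] = hi * hi;
  }
  for (int k = 0; k < contacts.nrow(); ++k) {
    int i = contacts(k, 0) - 1, j = contacts(k, 1) - 1;
    if (i > j) std::swap(i, j);
    size_t p = s.idx(i, j);
    if (s.ptype[p] == PT_BOND) stop("pair is both bond and contact");
    s.ptype[p] = PT_CONTACT;
    double lo = wellLow * contactD0[k], hi = wellHigh * contactD0[k];
    if (lo <= 0) stop("contact distance below hardcore diameter");
    s.rin2[p] = lo * lo;
    s.rout2[p] = hi * hi;
  }

  // initial overlap check + well occupancy
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j) {
      size_t p = s.idx(i, j);
      double r2 = s.dist2(i, j);
      if (r2 < s.rin2[p] * (1.0 - 1e-9))
        stop("bead overlap in initial state (pair %d,%d)", i + 1, j + 1);
      if (s.ptype[p] == PT_CONTACT && r2 < s.rout2[p]) {
        s.inWell[p] = 1;
        s.U -= eps;
      }
      if (s.ptype[p] == PT_BOND && r2 > s.rout2[p] * (1.0 + 1e-9))
        stop("bond outside its window in initial state (pair %d,%d)", i + 1, j + 1);
    }

  Rng rng(static_cast<uint64_t>(seed) * 0x9E3779B97F4A7C15ULL + 1ULL);

  if (initVel.isNotNull()) {
    NumericMatrix iv(initVel);
    if (iv.nrow() != N) stop("initVel dimension mismatch");
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) s.v[3 * i + d] = iv(i, d);
  } else {
    double sd = std::sqrt(temperature);
    double px = 0, py = 0, pz = 0;
    for (int i = 0; i < N; ++i) {
      s.v[3 * i] = sd * rng.gauss();
      s.v[3 * i + 1] = sd * rng.gauss();
      s.v[3 * i + 2] = sd * rng.gauss();
      px += s.v[3 * i]; py += s.v[3 * i + 1]; pz += s.v[3 * i + 2];
    }
    for (int i = 0; i < N; ++i) {  // remove net momentum
      s.v[3 * i] -= px / N;
      s.v[3 * i + 1] -= py / N;
      s.v[3 * i + 2] -= pz / N;
    }
  }

  // initial predictions
  for (int i = 0; i < N - 1; ++i)
    for (int j = i + 1; j < N; ++j) s.predict(i, j);

  double thermRate = thermostatRate * N;  // total Poisson rate
  double nextTherm = thermRate > 0 ? -std::log(rng.unif()) / thermRate : R_PosInf;

  long nFramesMax = (long)(nSteps / snapshotEvery) + 2;
  List frames(nFramesMax);
  std::vector<double> frameStep, frameE, frameK, frameT;
  int nFrames = 0;
  auto snapshot = [&](double step) {
    NumericMatrix fm(N, 3);
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) fm(i, d) = s.x[3 * i + d];
    frames[nFrames] = fm;
    frameStep.push_back(step);
    double K = s.kinetic();
    frameE.push_back(K + s.U);
    frameK.push_back(K);
    frameT.push_back(s.tcur);
    ++nFrames;
  };
  snapshot(0);

  long long step = 0;
  const long long nTotal = (long long)nSteps;
  while (step < nTotal) {
    bool haveQ = !s.queue.empty();
    double tq = haveQ ? s.queue.top().t : R_PosInf;
    if (!haveQ && !R_FINITE(nextTherm))
      stop("event-queue starvation: no future events (all beads at rest?)");
    if (nextTherm < tq) {
      s.advanceTo(nextTherm);
      int u = (int)(rng.unif() * N);
      if (u >= N) u = N - 1;
      double sd = std::sqrt(temperature);
      s.v[3 * u] = sd * rng.gauss();
      s.v[3 * u + 1] = sd * rng.gauss();
      s.v[3 * u + 2] = sd * rng.gauss();
      ++s.counter[u];
      s.predictAllFor(u);
      nextTherm = s.tcur - std::log(rng.unif()) / thermRate;
    } else {
      Event e = s.queue.top();
      s.queue.pop();
      if (e.ci != s.counter[e.i] || e.cj != s.counter[e.j]) continue;  // stale
      s.advanceTo(e.t);
      s.collide(e);
      s.predictAllFor(e.i);
      s.predictAllFor(e.j);
    }
    step += 1;
    if (step % snapshotEvery == 0) snapshot((double)step);
  }

  NumericMatrix finalV(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) finalV(i, d) = s.v[3 * i + d];

  List out = List::create(
      _["frames"] = frames[Range(0, nFrames - 1)],
      _["step"] = wrap(frameStep), _["energy"] = wrap(frameE),
      _["kinetic"] = wrap(frameK), _["time"] = wrap(frameT),
      _["finalVelocities"] = finalV, _["nEvents"] = step);
  return out;
}
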