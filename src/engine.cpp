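// Core generation loop of the individual-based simulator.
//
// The R level owns configuration, initialization and summaries; this file
// advances a simulation state by n generations, applying, in order per
// generation: the seasonal draw and fitness refresh, background mortality,
// reproduction (pathway choice, gamete sampling, seed formation and event
// classification), seed dispersal, simultaneous settlement with patch
// contention, lineage census / establishment detection, and ageing.
// All randomness comes from R's RNG so set.seed() fully determines a run.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Cfg {
  double svSd;
  double limits[5];
  double k4x;
  int combineRule;   // 1 geometric, 2 product, 3 min
  double mortality;
  int caps[3];
  int baseLifespan;
  double p2n2x, p2n4x;
  double triMix[4];  // x, 2x, 3x, aneuploid
  double triViab;
  int onset;
  double selfing[3], apomixis[3]; // by ploidy-2 index
  double lambdaPollen, pollenRadius;
  double lambdaSeed, seedRadius;
  int estThreshold;
  double segregationSd;
  double uniformE;   // NA -> environment-driven
  bool hasUniformE;
  bool globalPollen;
  NumericMatrix optimum; // n x 5 shifted-optimum layer values
};

struct Gamete {
  int dosage;      // multiples of x; 0 for aneuploid
  bool unreduced;
  bool aneuploid;
};

struct Seed {
  int ploidy;
  double ia[5];
  int eventType;    // 0 none, 1 bilateral, 2 unilateral
  bool eventNew;
  int inheritEvent; // -1 none
  int dx, dy;
};

enum Counter {
  C_G2X_RED, C_G2X_UNRED,
  C_G3X_X, C_G3X_2X, C_G3X_3X, C_G3X_ANEU,
  C_G4X_RED, C_G4X_UNRED,
  C_PATH_OUT, C_PATH_SELF, C_PATH_APO,
  C_POLLEN_LIMITED, C_SEEDS_FORMED,
  C_INVIABLE_ANEUPLOID, C_INVIABLE_OVER4X, C_TRIPLOID_BLOCK,
  C_SEEDS_OFF_GRID, C_SEEDS_ON_OCCUPIED, C_SEEDS_UNSUITABLE,
  C_ESTABLISHMENTS,
  C_SV_SUM, C_SV_SUMSQ, C_SV_N,
  C_N_COUNTERS
};

const char* counterNames[] = {
  "gamete_2x_reduced", "gamete_2x_unreduced",
  "gamete_3x_x", "gamete_3x_2x", "gamete_3x_3x", "gamete_3x_aneuploid",
  "gamete_4x_reduced", "gamete_4x_unreduced",
  "pathway_outcross", "pathway_self", "pathway_apomixis",
  "pollen_limited", "seeds_formed",
  "inviable_aneuploid", "inviable_over4x", "triploid_block_loss",
  "seeds_off_grid", "seeds_on_occupied", "seeds_unsuitable",
  "establishments",
  "sv_sum", "sv_sumsq", "sv_n"
};

inline Gamete sampleGamete(int ploidy, bool unreducedActive, const Cfg& cfg,
                           std::vector<double>& cnt) {
  Gamete g{1, false, false};
  if (ploidy == 2) {
    double p = unreducedActive ? cfg.p2n2x : 0.0;
    if (unif_rand() < p) { g.dosage = 2; g.unreduced = true; cnt[C_G2X_UNRED]++; }
    else { g.dosage = 1; cnt[C_G2X_RED]++; }
  } else if (ploidy == 3) {
    double u = unif_rand();
    if (u < cfg.triMix[0]) { g.dosage = 1; cnt[C_G3X_X]++; }
    else if (u < cfg.triMix[0] + cfg.triMix[1]) { g.dosage = 2; cnt[C_G3X_2X]++; }
    else if (u < cfg.triMix[0] + cfg.triMix[1] + cfg.triMix[2]) {
      g.dosage = 3; g.unreduced = true; cnt[C_G3X_3X]++;
    } else { g.dosage = 0; g.aneuploid = true; cnt[C_G3X_ANEU]++; }
  } else {
    if (unif_rand() < cfg.p2n4x) { g.dosage = 4; g.unreduced = true; cnt[C_G4X_UNRED]++; }
    else { g.dosage = 2; cnt[C_G4X_RED]++; }
  }
  return g;
}

Cfg parseCfg(List cfgL) {
  Cfg c;
  c.svSd = as<double>(cfgL["svSd"]);
  NumericVector lim = cfgL["limits"];
  for (int i = 0; i < 5; i++) c.limits[i] = lim[i];
  c.k4x = as<double>(cfgL["k4x"]);
  c.combineRule = as<int>(cfgL["combineRule"]);
  c.mortality = as<double>(cfgL["mortality"]);
  IntegerVector caps = cfgL["caps"];
  for (int i = 0; i < 3; i++) c.caps[i] = caps[i];
  c.baseLifespan = as<int>(cfgL["baseLifespan"]);
  c.p2n2x = as<double>(cfgL["p2n2x"]);
  c.p2n4x = as<double>(cfgL["p2n4x"]);
  NumericVector tm = cfgL["triMix"];
  for (int i = 0; i < 4; i++) c.triMix[i] = tm[i];
  c.triViab = as<double>(cfgL["triViab"]);
  c.onset = as<int>(cfgL["onset"]);
  NumericVector sf = cfgL["selfing"], ap = cfgL["apomixis"];
  for (int i = 0; i < 3; i++) { c.selfing[i] = sf[i]; c.apomixis[i] = ap[i]; }
  c.lambdaPollen = as<double>(cfgL["lambdaPollen"]);
  c.pollenRadius = as<double>(cfgL["pollenRadius"]);
  c.lambdaSeed = as<double>(cfgL["lambdaSeed"]);
  c.seedRadius = as<double>(cfgL["seedRadius"]);
  c.estThreshold = as<int>(cfgL["estThreshold"]);
  c.segregationSd = as<double>(cfgL["segregationSd"]);
  double ue = as<double>(cfgL["uniformE"]);
  c.hasUniformE = R_finite(ue);
  c.uniformE = ue;
  c.globalPollen = as<bool>(cfgL["globalPollen"]);
  c.optimum = as<NumericMatrix>(cfgL["optimum"]);
  return c;
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(List envL, List cfgL, List stateL, int nGens,
                  bool stopAtFixation, bool recordCensus) {
  Cfg cfg = parseCfg(cfgL);
  const int nx = as<int>(envL["nx"]);
  const int ny = as<int>(envL["ny"]);
  const NumericMatrix layers = envL["layers"]; // (nx*ny) x 5
  const int P = nx * ny;

  // ---- unpack state ----
  int generation = as<int>(stateL["generation"]);
  IntegerVector sx = stateL["x"], sy = stateL["y"],
    spl = stateL["ploidy"], sage = stateL["age"], smax = stateL["maxAge"],
    sev = stateL["eventId"];
  NumericMatrix sia = stateL["ia"];
  int n0 = sx.size();

  std::vector<int> px(sx.begin(), sx.end()), py(sy.begin(), sy.end()),
    ploidy(spl.begin(), spl.end()), age(sage.begin(), sage.end()),
    maxAge(smax.begin(), smax.end()), eventId(sev.begin(), sev.end());
  std::vector<double> ia(5 * n0);
  for (int i = 0; i < n0; i++)
    for (int k = 0; k < 5; k++) ia[5 * i + k] = sia(i, k);
  std::vector<double> evec(n0, 0.0);
  std::vector<char> alive(n0, 1);

  List evL = stateL["events"];
  IntegerVector evType0 = evL["type"], evGen0 = evL["genFormed"],
    evX0 = evL["x"], evY0 = evL["y"], evOut0 = evL["outcome"],
    evEst0 = evL["genEst"], evPl0 = evL["ploidy"];
  NumericVector evE0 = evL["founderE"];
  std::vector<int> evType(evType0.begin(), evType0.end()),
    evGen(evGen0.begin(), evGen0.end()), evX(evX0.begin(), evX0.end()),
    evY(evY0.begin(), evY0.end()), evOut(evOut0.begin(), evOut0.end()),
    evEst(evEst0.begin(), evEst0.end()),
    evPl(evPl0.begin(), evPl0.end());
  std::vector<double> evE(evE0.begin(), evE0.end());
  NumericVector evR0 = evL["relFitness"];
  std::vector<double> evRel(evR0.begin(), evR0.end());

  std::vector<double> cnt(C_N_COUNTERS, 0.0);
  NumericVector oldCnt = stateL["counters"];
  if (oldCnt.size() == C_N_COUNTERS)
    for (int i = 0; i < C_N_COUNTERS; i++) cnt[i] = oldCnt[i];

  std::vector<int> occupant(P, -1);
  for (int i = 0; i < n0; i++) occupant[px[i] + nx * py[i]] = i;

  // settlement scratch
  std::vector<int> bestSeed(P, -1), tieCount(P, 0);
  std::vector<double> bestE(P, -1.0);
  std::vector<int> touched;

  std::vector<double> cen2x, cen3x, cen4x, cenSv, cenGen;

  const double twoPi = 2.0 * M_PI;
  int stopReason = 2; // 1 fixation, 2 horizon, 3 extinct

  auto plantE = [&](int i, double sv) -> double {
    if (cfg.hasUniformE) return cfg.uniformE;
    const int p = px[i] + nx * py[i];
    double mult = (ploidy[i] == 4) ? cfg.k4x : 1.0;
    double sum = 0.0, mx = 0.0;
    for (int k = 0; k < 5; k++) {
      double v = layers(p, k);
      if (k < 3) v *= sv;
      double d = std::fabs(ia[5 * i + k] - v) / (cfg.limits[k] * mult);
      sum += d; if (d > mx) mx = d;
    }
    switch (cfg.combineRule) {
      case 1: return std::pow(2.0, -sum / 5.0);
      case 2: return std::pow(2.0, -sum);
      default: return std::pow(2.0, -mx);
    }
  };

  // suitability + prospective E of a seed genotype on a patch
  auto seedEval = [&](const Seed& s, double sv, double& Eout) -> bool {
    if (cfg.hasUniformE) { Eout = cfg.uniformE; return true; }
    const int p = s.dx + nx * s.dy;
    double mult = (s.ploidy == 4) ? cfg.k4x : 1.0;
    double sum = 0.0, mx = 0.0;
    bool ok = true;
    for (int k = 0; k < 5; k++) {
      double v = layers(p, k);
      if (k < 3) v *= sv;
      double d = std::fabs(s.ia[k] - v) / (cfg.limits[k] * mult);
      if (d > 1.0) { ok = false; break; }
      sum += d; if (d > mx) mx = d;
    }
    if (!ok) return false;
    switch (cfg.combineRule) {
      case 1: Eout = std::pow(2.0, -sum / 5.0); break;
      case 2: Eout = std::pow(2.0, -sum); break;
      default: Eout = std::pow(2.0, -mx); break;
    }
    return true;
  };

  std::vector<Seed> seeds;
  std::vector<int> living;   // indices of living plants (donor pool)
  std::vector<int> nbr; std::vector<double> nbrW;

  for (int g = 0; g < nGens; g++) {
    const int curGen = generation + 1;
    const bool unredActive = curGen >= cfg.onset;

    // (1) seasonal factor + fitness refresh
    const double sv = 1.0 + cfg.svSd * norm_rand();
    cnt[C_SV_SUM] += sv; cnt[C_SV_SUMSQ] += sv * sv; cnt[C_SV_N] += 1.0;
    const int nP = (int)px.size();
    for (int i = 0; i < nP; i++) if (alive[i]) evec[i] = plantE(i, sv);

    // (2) background mortality
    for (int i = 0; i < nP; i++) {
      if (!alive[i]) continue;
      if (unif_rand() < cfg.mortality) {
        alive[i] = 0;
        occupant[px[i] + nx * py[i]] = -1;
      }
    }

    living.clear();
    for (int i = 0; i < nP; i++) if (alive[i]) living.push_back(i);

    // (3) reproduction
    seeds.clear();
    for (int idx = 0; idx < (int)living.size(); idx++) {
      const int i = living[idx];
      if (age[i] < 1) continue;
      const int cap = cfg.caps[std::min(age[i], 3) - 1];
      const int nov = (int)R::rbinom(cap, evec[i]);
      if (nov == 0) continue;
      const int plI = ploidy[i] - 2; // 0..2
      bool nbrReady = false;

      for (int o = 0; o < nov; o++) {
        const double u = unif_rand();
        int pathway; // 0 outcross, 1 self, 2 apomixis
        if (u < cfg.selfing[plI]) pathway = 1;
        else if (u < cfg.selfing[plI] + cfg.apomixis[plI]) pathway = 2;
        else pathway = 0;

        Seed s;
        if (pathway == 2) {
          cnt[C_PATH_APO]++;
          s.ploidy = ploidy[i];
          for (int k = 0; k < 5; k++) s.ia[k] = ia[5 * i + k];
          s.eventType = 0; s.eventNew = false;
          s.inheritEvent = (ploidy[i] >= 3) ? eventId[i] : -1;
          if (s.ploidy == 3 && cfg.triViab < 1.0) {
            if (unif_rand() >= cfg.triViab) { cnt[C_TRIPLOID_BLOCK]++; continue; }
          }
        } else {
          int donor;
          if (pathway == 1) { cnt[C_PATH_SELF]++; donor = i; }
          else {
            cnt[C_PATH_OUT]++;
            if (cfg.globalPollen) {
              if (living.size() < 2) { cnt[C_POLLEN_LIMITED]++; continue; }
              do {
                donor = living[(int)(unif_rand() * living.size()) % living.size()];
              } while (donor == i);
            } else {
              if (!nbrReady) {
                nbr.clear(); nbrW.clear();
                const int R10 = (int)std::ceil(cfg.pollenRadius);
                const double r2 = cfg.pollenRadius * cfg.pollenRadius;
                double cum = 0.0;
                for (int yy = std::max(0, py[i] - R10);
                     yy <= std::min(ny - 1, py[i] + R10); yy++)
                  for (int xx = std::max(0, px[i] - R10);
                       xx <= std::min(nx - 1, px[i] + R10); xx++) {
                    const int j = occupant[xx + nx * yy];
                    if (j < 0 || j == i) continue;
                    const double d2 = (double)(xx - px[i]) * (xx - px[i]) +
                                      (double)(yy - py[i]) * (yy - py[i]);
                    if (d2 > r2) continue;
                    cum += std::exp(-std::sqrt(d2) / cfg.lambdaPollen);
                    nbr.push_back(j); nbrW.push_back(cum);
                  }
                nbrReady = true;
              }
              if (nbr.empty()) { cnt[C_POLLEN_LIMITED]++; continue; }
              const double target = unif_rand() * nbrW.back();
              int lo = 0, hi = (int)nbr.size() - 1;
              while (lo < hi) {
                const int mid = (lo + hi) / 2;
                if (nbrW[mid] < target) lo = mid + 1; else hi = mid;
              }
              donor = nbr[lo];
            }
          }
          const Gamete f = sampleGamete(ploidy[i], unredActive, cfg, cnt);
          const Gamete m = sampleGamete(ploidy[donor], unredActive, cfg, cnt);
          if (f.aneuploid || m.aneuploid) { cnt[C_INVIABLE_ANEUPLOID]++; continue; }
          const int sum = f.dosage + m.dosage;
          if (sum > 4) { cnt[C_INVIABLE_OVER4X]++; continue; }
          const bool triAssoc = (sum == 3) || ploidy[i] == 3 || ploidy[donor] == 3;
          if (triAssoc && cfg.triViab < 1.0) {
            if (unif_rand() >= cfg.triViab) { cnt[C_TRIPLOID_BLOCK]++; continue; }
          }
          const int nu = (f.unreduced ? 1 : 0) + (m.unreduced ? 1 : 0);
          s.ploidy = sum;
          s.eventType = (nu == 2) ? 1 : (nu == 1 ? 2 : 0);
          s.eventNew = s.eventType > 0 &&
            (sum == 3 || (sum == 4 && !(ploidy[i] == 4 && ploidy[donor] == 4)));
          for (int k = 0; k < 5; k++) {
            double v = 0.5 * (ia[5 * i + k] + ia[5 * donor + k]);
            if (cfg.segregationSd > 0) v += cfg.segregationSd * norm_rand();
            s.ia[k] = v;
          }
          if (s.eventNew && sum == 4 && cfg.optimum.nrow() > 0) {
            const int r = (int)(unif_rand() * cfg.optimum.nrow()) %
                          cfg.optimum.nrow();
            for (int k = 0; k < 5; k++) s.ia[k] = cfg.optimum(r, k);
          }
          if (s.eventNew) s.inheritEvent = -1;
          else if (sum >= 3) {
            if (ploidy[i] >= 3 && (sum != 4 || ploidy[i] == 4))
              s.inheritEvent = eventId[i];
            else if (ploidy[donor] >= 3 && (sum != 4 || ploidy[donor] == 4))
              s.inheritEvent = eventId[donor];
            else if (ploidy[i] >= 3) s.inheritEvent = eventId[i];
            else if (ploidy[donor] >= 3) s.inheritEvent = eventId[donor];
            else s.inheritEvent = -1;
          } else s.inheritEvent = -1;
        }
        cnt[C_SEEDS_FORMED]++;

        // (4) dispersal
        double dd = R::exp_rand() * cfg.lambdaSeed;
        int tries = 0;
        while (dd > cfg.seedRadius && tries < 100) {
          dd = R::exp_rand() * cfg.lambdaSeed; tries++;
        }
        const double a = unif_rand() * twoPi;
        const int dx = (int)std::lround(px[i] + dd * std::cos(a));
        const int dy = (int)std::lround(py[i] + dd * std::sin(a));
        if (dx < 0 || dy < 0 || dx >= nx || dy >= ny) {
          cnt[C_SEEDS_OFF_GRID]++; continue;
        }
        s.dx = dx; s.dy = dy;
        seeds.push_back(s);
      }
    }

    // (5) simultaneous settlement with contention
    touched.clear();
    std::vector<double> seedE(seeds.size());
    for (int sI = 0; sI < (int)seeds.size(); sI++) {
      const Seed& s = seeds[sI];
      const int p = s.dx + nx * s.dy;
      if (occupant[p] >= 0) { cnt[C_SEEDS_ON_OCCUPIED]++; continue; }
      double E;
      if (!seedEval(s, sv, E)) { cnt[C_SEEDS_UNSUITABLE]++; continue; }
      seedE[sI] = E;
      if (bestSeed[p] < 0) {
        bestSeed[p] = sI; bestE[p] = E; tieCount[p] = 1;
        touched.push_back(p);
      } else if (E > bestE[p]) {
        bestSeed[p] = sI; bestE[p] = E; tieCount[p] = 1;
      } else if (E == bestE[p]) {
        tieCount[p]++;
        if (unif_rand() < 1.0 / tieCount[p]) bestSeed[p] = sI;
      }
    }
    for (int t = 0; t < (int)touched.size(); t++) {
      const int p = touched[t];
      const int sI = bestSeed[p];
      const Seed& s = seeds[sI];
      const double E = bestE[p];
      int eid = s.inheritEvent;
      if (s.eventNew) {
        eid = (int)evType.size();
        evType.push_back(s.eventType);
        evPl.push_back(s.ploidy);
        evGen.push_back(curGen);
        evX.push_back(s.dx); evY.push_back(s.dy);
        evE.push_back(E);
        evOut.push_back(0); evEst.push_back(-1);
        // fitness relative to the surrounding diploids (radius 5)
        double sumE = 0.0; int nD = 0;
        for (int yy = std::max(0, s.dy - 5);
             yy <= std::min(ny - 1, s.dy + 5); yy++)
          for (int xx = std::max(0, s.dx - 5);
               xx <= std::min(nx - 1, s.dx + 5); xx++) {
            const int j = occupant[xx + nx * yy];
            if (j >= 0 && ploidy[j] == 2 &&
                (xx - s.dx) * (xx - s.dx) + (yy - s.dy) * (yy - s.dy) <= 25) {
              sumE += evec[j]; nD++;
            }
          }
        evRel.push_back(nD > 0 ? E - sumE / nD : NA_REAL);
      }
      px.push_back(s.dx); py.push_back(s.dy);
      ploidy.push_back(s.ploidy);
      age.push_back(1);
      maxAge.push_back(std::max(1, (int)std::ceil(cfg.baseLifespan * E)));
      for (int k = 0; k < 5; k++) ia.push_back(s.ia[k]);
      eventId.push_back(eid);
      evec.push_back(E);
      alive.push_back(1);
      occupant[p] = (int)px.size() - 1;
      cnt[C_ESTABLISHMENTS]++;
      bestSeed[p] = -1; bestE[p] = -1.0; tieCount[p] = 0;
    }

    // (6) lineage census and establishment detection
    if (!evType.empty()) {
      std::vector<int> lc(evType.size(), 0);
      for (int i = 0; i < (int)px.size(); i++)
        if (alive[i] && ploidy[i] == 4 && eventId[i] >= 0) lc[eventId[i]]++;
      for (int e2 = 0; e2 < (int)evType.size(); e2++)
        if (evOut[e2] == 0 && lc[e2] >= cfg.estThreshold) {
          evOut[e2] = 1; evEst[e2] = curGen;
        }
    }

    // (7) ageing of pre-existing survivors (recruits keep age 1)
    for (int i = 0; i < nP; i++) {
      if (!alive[i]) continue;
      age[i] += 1;
      if (age[i] > maxAge[i]) {
        alive[i] = 0;
        occupant[px[i] + nx * py[i]] = -1;
      }
    }

    generation = curGen;

    // census + stop rules
    int n2 = 0, n3 = 0, n4 = 0;
    for (int i = 0; i < (int)px.size(); i++) {
      if (!alive[i]) continue;
      if (ploidy[i] == 2) n2++; else if (ploidy[i] == 3) n3++; else n4++;
    }
    if (recordCensus) {
      cenGen.push_back(generation);
      cen2x.push_back(n2); cen3x.push_back(n3); cen4x.push_back(n4);
      cenSv.push_back(sv);
    }
    const int tot = n2 + n3 + n4;
    if (tot == 0) { stopReason = 3; if (stopAtFixation) break; }
    if (tot > 0 && stopAtFixation && n4 == tot) { stopReason = 1; break; }

    // compact the plant arrays
    if ((int)px.size() > tot) {
      std::vector<int> keep; keep.reserve(tot);
      for (int i = 0; i < (int)px.size(); i++) if (alive[i]) keep.push_back(i);
      for (int j = 0; j < tot; j++) {
        const int i = keep[j];
        px[j] = px[i]; py[j] = py[i]; ploidy[j] = ploidy[i];
        age[j] = age[i]; maxAge[j] = maxAge[i]; eventId[j] = eventId[i];
        evec[j] = evec[i];
        for (int k = 0; k < 5; k++) ia[5 * j + k] = ia[5 * i + k];
      }
      px.resize(tot); py.resize(tot); ploidy.resize(tot); age.resize(tot);
      maxAge.resize(tot); eventId.resize(tot); evec.resize(tot);
      ia.resize(5 * tot);
      alive.assign(tot, 1);
      std::fill(occupant.begin(), occupant.end(), -1);
      for (int i = 0; i < tot; i++) occupant[px[i] + nx * py[i]] = i;
    }
  }

  // ---- repack state ----
  const int nEnd = (int)px.size();
  std::vector<int> keep; keep.reserve(nEnd);
  for (int i = 0; i < nEnd; i++) if (alive[i]) keep.push_back(i);
  const int nOut = (int)keep.size();
  IntegerVector ox(nOut), oy(nOut), opl(nOut), oage(nOut), omax(nOut),
    oev(nOut);
  NumericVector oe(nOut);
  NumericMatrix oia(nOut, 5);
  for (int j = 0; j < nOut; j++) {
    const int i = keep[j];
    ox[j] = px[i]; oy[j] = py[i]; opl[j] = ploidy[i]; oage[j] = age[i];
    omax[j] = maxAge[i]; oev[j] = eventId[i]; oe[j] = evec[i];
    for (int k = 0; k < 5; k++) oia(j, k) = ia[5 * i + k];
  }
  NumericVector outCnt(C_N_COUNTERS);
  CharacterVector cn(C_N_COUNTERS);
  for (int i = 0; i < C_N_COUNTERS; i++) {
    outCnt[i] = cnt[i]; cn[i] = counterNames[i];
  }
  outCnt.names() = cn;

  List events = List::create(
    _["type"] = wrap(evType), _["ploidy"] = wrap(evPl),
    _["genFormed"] = wrap(evGen),
    _["x"] = wrap(evX), _["y"] = wrap(evY),
    _["founderE"] = wrap(evE), _["relFitness"] = wrap(evRel),
    _["outcome"] = wrap(evOut),
    _["genEst"] = wrap(evEst));

  List state = List::create(
    _["generation"] = generation,
    _["x"] = ox, _["y"] = oy, _["ploidy"] = opl, _["age"] = oage,
    _["maxAge"] = omax, _["ia"] = oia, _["eventId"] = oev, _["e"] = oe,
    _["events"] = events, _["counters"] = outCnt);

  List census = List::create(
    _["generation"] = wrap(cenGen), _["n2x"] = wrap(cen2x),
    _["n3x"] = wrap(cen3x), _["n4x"] = wrap(cen4x), _["sv"] = wrap(cenSv));

  return List::create(_["state"] = state, _["census"] = census,
                      _["stopReason"] = stopReason);
}
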