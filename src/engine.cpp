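#include "engine.h"
#include <map>
#include <array>
#include <utility>
using namespace Rcpp;

// Cellular Potts engine: lattice state, incremental Hamiltonian, Metropolis
// pixel-copy dynamics, and the per-MCS biological rule pipeline
// (field -> chemical-death check -> growth -> differentiation -> mitosis ->
//  sloughing -> Metropolis -> tear re-wetting).

static const int DX8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
static const int DY8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
static const int DX4[4] = {1, -1, 0, 0};
static const int DY4[4] = {0, 0, 1, -1};

// The Metropolis decision: accept when the energy does not increase, else
// with Boltzmann probability exp(-dH/T).
static inline bool metropolis_accept(double dH, double T, RunRNG& rng) {
  return dH <= 0.0 || rng.unif() < std::exp(-dH / T);
}

// Event codes written to the run event log.
enum EventCode {
  EV_DIVISION = 1, EV_SLOUGH = 2, EV_CHEM_MARK = 3, EV_DEATH = 4,
  EV_MEMB_DESTROYED = 5, EV_DIFFERENTIATION = 7
};

struct FieldSpec {
  bool on = false;
  double d_global = 186.0, d_super = 20.0, d_memb = 20.0, d_limb = 0.0;
  double decay = 0.5;
  int n_sub = 10;
  bool clamp_tear = false;
  double clamp_value = 1.0;
  bool dirichlet_tb = true;
};

static FieldSpec parse_field_spec(List par) {
  FieldSpec f;
  f.on = true;
  f.d_global = as<double>(par["d_global"]);
  f.d_super = as<double>(par["d_super"]);
  f.d_memb = as<double>(par["d_memb"]);
  f.d_limb = as<double>(par["d_limb"]);
  f.decay = as<double>(par["decay"]);
  f.n_sub = as<int>(par["n_sub"]);
  f.clamp_tear = as<bool>(par["clamp_tear"]);
  f.clamp_value = as<double>(par["clamp_value"]);
  f.dirichlet_tb = as<std::string>(par["boundary"]) == "paper";
  return f;
}

class Engine {
public:
  int W = 0, H = 0;
  std::vector<int> owner;
  int next_id = 1;
  int mcs = 0;

  // registry, indexed by cell id
  std::vector<int> ctype_, vol, surf, age_, parent_;
  std::vector<double> tvol, sumx, sumy, anchx, anchy;
  std::vector<signed char> alive, dying, anchored;  // anchored: 0/1, 2 = broken

  // Potts parameters
  double J[NTYPES][NTYPES];
  double lamv[NTYPES], lams[NTYPES], mu[NTYPES];
  double temperature = 10.0, lam_link = 0.0, link_rest = 0.0;
  double surf_fac[NTYPES];

  // rule parameters
  double km_egf = 0.3, km_egf_stem = 0.3, km_density = 8.0, delta_max = 0.3125;
  int hill_n = 4, mitosis_volume = 50, omega_contact_basal = 5;
  double slough_prob = 1.0 / 720.0;
  int tear_thickness = 4;
  double tox_kill_threshold = 1e300;

  // fields
  FieldSpec egf_spec, tox_spec;
  std::vector<double> egf, tox;

  // per-MCS scratch, indexed by id
  std::vector<double> egfavg, toxavg;
  std::vector<uint32_t> nbrmask;
  std::vector<int> aepbm;
  std::vector<signed char> tearct;

  // run bookkeeping
  std::vector<double> ev_mcs, ev_code, ev_id, ev_a, ev_b, ev_type;
  std::vector<double> cs_mcs, cs_id, cs_type, cs_x, cs_y, cs_vol, cs_egf;
  long attempts = 0, accepts = 0;
  int killed_by_type[NTYPES] = {0};
  int memb_destroyed = 0;
  int tear_id = -1, dmg_id = -1;

  inline int idx(int x, int y) const { return x + y * W; }
  inline int ct(int id) const { return id == 0 ? T_AIR : ctype_[id]; }
  inline double surf_target(int id) const {
    return surf_fac[ctype_[id]] * std::sqrt(std::max(tvol[id], 0.0));
  }

  void ensure_capacity(int n) {
    if ((int)ctype_.size() >= n) return;
    ctype_.resize(n, T_AIR); vol.resize(n, 0); surf.resize(n, 0);
    age_.resize(n, 0); parent_.resize(n, 0);
    tvol.resize(n, 0.0); sumx.resize(n, 0.0); sumy.resize(n, 0.0);
    anchx.resize(n, 0.0); anchy.resize(n, 0.0);
    alive.resize(n, 0); dying.resize(n, 0); anchored.resize(n, 0);
  }

  void load(List state, List potts, List rules, Nullable<List> egf_par,
            Nullable<List> tox_par) {
    IntegerMatrix og = state["owner"];
    W = og.nrow(); H = og.ncol();
    owner.assign(W * H, 0);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) owner[idx(x, y)] = og(x, y);
    mcs = as<int>(state["mcs"]);
    next_id = as<int>(state["next_id"]);
    ensure_capacity(next_id + 64);

    List cells = state["cells"];
    IntegerVector id = cells["id"], type = cells["type"], agev = cells["age"],
                  parv = cells["parent"];
    NumericVector tv = cells["target_volume"], ax = cells["anchor_x"],
                  ay = cells["anchor_y"];
    IntegerVector dy = cells["dying"], an = cells["anchored"];
    for (int i = 0; i < id.size(); ++i) {
      int c = id[i];
      if (c <= 0 || c >= next_id) stop("cell id out of range");
      ctype_[c] = type[i]; tvol[c] = tv[i]; age_[c] = agev[i];
      dying[c] = (signed char)dy[i]; anchored[c] = (signed char)an[i];
      anchx[c] = ax[i]; anchy[c] = ay[i]; parent_[c] = parv[i];
      alive[c] = 1;
      if (type[i] == T_TEAR) tear_id = c;
      if (type[i] == T_DMG) dmg_id = c;
    }

    NumericMatrix Jm = potts["J"];
    for (int a = 0; a < NTYPES; ++a)
      for (int b = 0; b < NTYPES; ++b) J[a][b] = Jm(a, b);
    NumericVector lv = potts["lambda_volume"], ls = potts["lambda_surface"],
                  muv = potts["chemotaxis_mu"];
    for (int a = 0; a < NTYPES; ++a) {
      lamv[a] = lv[a]; lams[a] = ls[a]; mu[a] = muv[a];
    }
    temperature = as<double>(potts["temperature"]);
    NumericVector sf = potts["surface_factor"];
    for (int a = 0; a < NTYPES; ++a)
      surf_fac[a] = sf.size() == 1 ? sf[0] : sf[a];
    lam_link = as<double>(potts["lambda_link"]);
    link_rest = as<double>(potts["link_rest"]);

    km_egf = as<double>(rules["km_egf"]);
    km_egf_stem = as<double>(rules["km_egf_stem"]);
    km_density = as<double>(rules["km_density"]);
    hill_n = as<int>(rules["hill_n"]);
    delta_max = as<double>(rules["delta_max"]);
    mitosis_volume = as<int>(rules["mitosis_volume"]);
    omega_contact_basal = as<int>(rules["omega_contact_basal"]);
    slough_prob = as<double>(rules["slough_prob"]);
    tear_thickness = as<int>(rules["tear_thickness"]);

    egf.assign(W * H, 0.0);
    if (egf_par.isNotNull()) {
      egf_spec = parse_field_spec(egf_par.get());
      NumericMatrix em = state["egf"];
      for (int y = 0; y < H; ++y)
        for (int x = 0; x < W; ++x) egf[idx(x, y)] = em(x, y);
    }
    tox.assign(W * H, 0.0);
    if (tox_par.isNotNull()) {
      List tp = tox_par.get();
      tox_spec = parse_field_spec(tp);
      tox_kill_threshold = as<double>(tp["kill_threshold"]);
      RObject tm = state["tox"];
      if (!tm.isNULL()) {
        NumericMatrix t2 = as<NumericMatrix>(tm);
        for (int y = 0; y < H; ++y)
          for (int x = 0; x < W; ++x) tox[idx(x, y)] = t2(x, y);
      }
    }
    recompute(false);
    for (int c = 1; c < next_id; ++c)
      if (vol[c] > 0 && !alive[c])
        stop("owner grid references a cell id missing from the registry");
  }

  // Full-rescan bookkeeping: volumes, boundary-face counts, COM sums.
  // Cells whose volume reached zero are removed from the registry.
  void recompute(bool log_deaths) {
    std::vector<signed char> was(alive);
    for (int c = 0; c < next_id; ++c) { vol[c] = 0; surf[c] = 0; sumx[c] = 0; sumy[c] = 0; }
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int o = owner[idx(x, y)];
        if (o == 0) continue;
        vol[o]++; sumx[o] += x; sumy[o] += y;
        for (int k = 0; k < 4; ++k) {
          int nx = x + DX4[k], ny = y + DY4[k];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H || owner[idx(nx, ny)] != o)
            surf[o]++;
        }
      }
    for (int c = 1; c < next_id; ++c) {
      if (was[c] && vol[c] == 0) {
        alive[c] = 0;
        if (log_deaths) log_event(EV_DEATH, c, 0, 0);
      }
    }
  }

  void log_event(int code, int id, double a, double b) {
    ev_mcs.push_back(mcs); ev_code.push_back(code); ev_id.push_back(id);
    ev_a.push_back(a); ev_b.push_back(b);
    ev_type.push_back(id > 0 && id < next_id ? ctype_[id] : T_AIR);
  }

  // ---- Hamiltonian -------------------------------------------------------

  // Exact energy change if the owner of (qx,qy) were overwritten by the
  // owner of (px,py). dSs/dSt return the boundary-face changes for reuse.
  double delta_h(int px, int py, int qx, int qy, int* dSs_out, int* dSt_out) const {
    int s = owner[idx(px, py)], t = owner[idx(qx, qy)];
    int ts = ct(s), tt = ct(t);
    double dH = 0.0;

    for (int k = 0; k < 8; ++k) {
      int nx = qx + DX8[k], ny = qy + DY8[k];
      if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
      int o = owner[idx(nx, ny)];
      int to = ct(o);
      if (o != s) dH += J[ts][to];
      if (o != t) dH -= J[tt][to];
    }

    if (s != 0 && lamv[ts] > 0) {
      double v = vol[s], v0 = tvol[s];
      dH += lamv[ts] * ((v + 1 - v0) * (v + 1 - v0) - (v - v0) * (v - v0));
    }
    if (t != 0 && lamv[tt] > 0) {
      double v = vol[t], v0 = tvol[t];
      dH += lamv[tt] * ((v - 1 - v0) * (v - 1 - v0) - (v - v0) * (v - v0));
    }

    int dSs = 0, dSt = 0;
    for (int k = 0; k < 4; ++k) {
      int nx = qx + DX4[k], ny = qy + DY4[k];
      int o = (nx < 0 || nx >= W || ny < 0 || ny >= H) ? -1 : owner[idx(nx, ny)];
      dSs += (o == s) ? -1 : 1;
      dSt += (o == t) ? 1 : -1;
    }
    if (dSs_out) *dSs_out = dSs;
    if (dSt_out) *dSt_out = dSt;
    if (s != 0 && lams[ts] > 0) {
      double S = surf[s], S0 = surf_target(s);
      dH += lams[ts] * ((S + dSs - S0) * (S + dSs - S0) - (S - S0) * (S - S0));
    }
    if (t != 0 && lams[tt] > 0) {
      double S = surf[t], S0 = surf_target(t);
      dH += lams[tt] * ((S + dSt - S0) * (S + dSt - S0) - (S - S0) * (S - S0));
    }

    // chemotaxis of the invading cell on the EGF field
    if (egf_spec.on && s != 0 && mu[ts] != 0.0)
      dH += -mu[ts] * (egf[idx(qx, qy)] - egf[idx(px, py)]);

    // adhesion springs (hemidesmosome proxy) respond to COM displacement
    if (lam_link > 0) {
      if (s != 0 && anchored[s] == 1) {
        double v = vol[s];
        double ox = sumx[s] / v - anchx[s], oy = sumy[s] / v - anchy[s];
        double nx2 = (sumx[s] + qx) / (v + 1) - anchx[s],
               ny2 = (sumy[s] + qy) / (v + 1) - anchy[s];
        double d0 = std::sqrt(ox * ox + oy * oy) - link_rest;
        double d1 = std::sqrt(nx2 * nx2 + ny2 * ny2) - link_rest;
        dH += lam_link * (d1 * d1 - d0 * d0);
      }
      if (t != 0 && anchored[t] == 1) {
        double v = vol[t];
        double ox = sumx[t] / v - anchx[t], oy = sumy[t] / v - anchy[t];
        double d0 = std::sqrt(ox * ox + oy * oy) - link_rest;
        if (v > 1) {
          double nx2 = (sumx[t] - qx) / (v - 1) - anchx[t],
                 ny2 = (sumy[t] - qy) / (v - 1) - anchy[t];
          double d1 = std::sqrt(nx2 * nx2 + ny2 * ny2) - link_rest;
          dH += lam_link * (d1 * d1 - d0 * d0);
        } else {
          dH -= lam_link * d0 * d0;  // last pixel: the spring disappears
        }
      }
    }
    return dH;
  }

  // ---- Metropolis --------------------------------------------------------

  void metropolis_sweep(RunRNG& rng) {
    std::vector<int> eligible;
    eligible.reserve(W * H / 2);
    for (int i = 0; i < W * H; ++i)
      if (type_is_mobile(ct(owner[i]))) eligible.push_back(i);
    int n_att = (int)eligible.size();
    for (int a = 0; a < n_att; ++a) {
      int q = eligible[rng.below(n_att)];
      int qx = q % W, qy = q / W;
      int t = owner[q];
      if (!type_is_mobile(ct(t))) continue;  // stale entry
      int k = rng.below(8);
      int px = qx + DX8[k], py = qy + DY8[k];
      if (px < 0 || px >= W || py < 0 || py >= H) continue;
      int s = owner[idx(px, py)];
      if (s == t || !type_is_mobile(ct(s))) continue;
      attempts++;
      int dSs, dSt;
      double dH = delta_h(px, py, qx, qy, &dSs, &dSt);
      if (!metropolis_accept(dH, temperature, rng)) continue;
      accepts++;
      owner[q] = s;
      vol[s]++; sumx[s] += qx; sumy[s] += qy; surf[s] += dSs;
      vol[t]--; sumx[t] -= qx; sumy[t] -= qy; surf[t] += dSt;
      if (vol[t] == 0) {
        alive[t] = 0;
        log_event(EV_DEATH, t, 0, 0);
      }
    }
  }

  // ---- per-MCS rule passes ----------------------------------------------

  // One sweep collecting, for every epithelial cell: mean field levels,
  // the set of contacting neighbour types (8-neighbourhood), the number of
  // boundary pixels touching the basement membrane, and tear contact.
  void rule_pass() {
    egfavg.assign(next_id, 0.0);
    toxavg.assign(next_id, 0.0);
    nbrmask.assign(next_id, 0u);
    aepbm.assign(next_id, 0);
    tearct.assign(next_id, 0);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int o = owner[idx(x, y)];
        if (o == 0 || !type_is_epithelial(ctype_[o])) continue;
        egfavg[o] += egf[idx(x, y)];
        if (tox_spec.on) toxavg[o] += tox[idx(x, y)];
        bool membrane_here = false;
        for (int k = 0; k < 8; ++k) {
          int nx = x + DX8[k], ny = y + DY8[k];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int n = owner[idx(nx, ny)];
          if (n == o) continue;
          int tn = ct(n);
          nbrmask[o] |= (1u << tn);
          if (tn == T_LIMB || tn == T_MEMB) membrane_here = true;
          if (tn == T_TEAR) tearct[o] = 1;
        }
        if (membrane_here) aepbm[o]++;
      }
    for (int c = 1; c < next_id; ++c)
      if (alive[c] && vol[c] > 0) {
        egfavg[c] /= vol[c];
        toxavg[c] /= vol[c];
      }
  }

  void step_fields() {
    std::vector<unsigned char> clamp(W * H, 0);
    if (egf_spec.on) {
      std::vector<double> dmap(W * H);
      for (int i = 0; i < W * H; ++i) {
        int t = ct(owner[i]);
        double D = egf_spec.d_global;
        if (t == T_SUPER) D = egf_spec.d_super;
        else if (t == T_MEMB) D = egf_spec.d_memb;
        else if (t == T_LIMB) D = egf_spec.d_limb;
        else if (t == T_WALL) D = 0.0;
        dmap[i] = D;
        clamp[i] = (egf_spec.clamp_tear && t == T_TEAR) ? 1 : 0;
      }
      double dt = 1.0 / egf_spec.n_sub;
      for (int s = 0; s < egf_spec.n_sub; ++s)
        field_substep(egf, dmap, clamp, egf_spec.clamp_value, egf_spec.decay,
                      dt, W, H, egf_spec.dirichlet_tb);
    }
    if (tox_spec.on) {
      // a fully decayed toxicant field has no sources and stays zero
      bool any = false;
      for (int i = 0; i < W * H && !any; ++i)
        if (tox[i] > 0.0) any = true;
      if (!any) return;
      std::vector<double> dmap(W * H);
      std::vector<unsigned char> noclamp(W * H, 0);
      for (int i = 0; i < W * H; ++i) {
        int t = ct(owner[i]);
        double D = tox_spec.d_global;
        if (t == T_SUPER) D = tox_spec.d_super;
        else if (t == T_MEMB) D = tox_spec.d_memb;
        else if (t == T_LIMB) D = tox_spec.d_limb;
        else if (t == T_WALL) D = 0.0;
        dmap[i] = D;
      }
      double dt = 1.0 / tox_spec.n_sub;
      for (int s = 0; s < tox_spec.n_sub; ++s)
        field_substep(tox, dmap, noclamp, 0.0, tox_spec.decay, dt, W, H,
                      tox_spec.dirichlet_tb);
    }
  }

  // Concentration-triggered death: epithelial cells above threshold shrink
  // to zero target volume; membrane pixels above threshold are permanently
  // converted to a passive damaged state (no regeneration).
  void chemical_kill() {
    if (!tox_spec.on) return;
    for (int c = 1; c < next_id; ++c) {
      if (!alive[c] || dying[c] || !type_is_epithelial(ctype_[c])) continue;
      if (toxavg[c] > tox_kill_threshold) {
        dying[c] = 1;
        tvol[c] = 0.0;
        killed_by_type[ctype_[c]]++;
        log_event(EV_CHEM_MARK, c, toxavg[c], 0);
      }
    }
    bool changed = false;
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int o = owner[idx(x, y)];
        if (o == 0) continue;
        int t = ctype_[o];
        if ((t == T_LIMB || t == T_MEMB) && tox[idx(x, y)] > tox_kill_threshold) {
          if (dmg_id < 0) {
            dmg_id = next_id++;
            ensure_capacity(next_id + 64);
            ctype_[dmg_id] = T_DMG; alive[dmg_id] = 1; tvol[dmg_id] = 0.0;
          }
          owner[idx(x, y)] = dmg_id;
          memb_destroyed++;
          killed_by_type[t]++;
          log_event(EV_MEMB_DESTROYED, dmg_id, x, y);
          changed = true;
        }
      }
    if (changed) recompute(true);
  }

  void growth() {
    for (int c = 1; c < next_id; ++c) {
      if (!alive[c] || dying[c]) continue;
      int t = ctype_[c];
      if (t != T_STEM && t != T_BASAL) continue;
      double P = lamv[t] * (tvol[c] - vol[c]);
      if (P < 0) P = 0;
      double km = (t == T_STEM) ? km_egf_stem : km_egf;
      double re = (km > 0) ? egfavg[c] / km : 1e12;
      double rp = (km_density > 0) ? P / km_density : 0.0;
      double re_n = std::pow(re, hill_n), rp_n = std::pow(rp, hill_n);
      double g_egf = re_n / (1.0 + re_n);
      double g_den = 1.0 / (1.0 + rp_n);
      tvol[c] += delta_max * g_egf * g_den;
    }
  }

  void differentiate() {
    // decisions from the rule_pass snapshot, applied simultaneously
    std::vector<std::pair<int, int>> trans;
    for (int c = 1; c < next_id; ++c) {
      if (!alive[c] || dying[c] || !type_is_epithelial(ctype_[c])) continue;
      int t = ctype_[c];
      uint32_t m = nbrmask[c];
      if (t == T_STEM && !(m & (1u << T_LIMB)))
        trans.push_back({c, T_BASAL});
      else if (t == T_BASAL && aepbm[c] <= omega_contact_basal)
        trans.push_back({c, T_WING});
      else if (t == T_WING && (m & (1u << T_TEAR)) && (m & (1u << T_WING)) &&
               !(m & ((1u << T_BASAL) | (1u << T_MEMB) | (1u << T_STEM))))
        trans.push_back({c, T_SUPER});
    }
    for (auto& tr : trans) {
      log_event(EV_DIFFERENTIATION, tr.first, ctype_[tr.first], tr.second);
      ctype_[tr.first] = tr.second;
    }
  }

  // Split one cell by a cleavage line through its COM with unit normal
  // (nx, ny); pixels on the line alternate between daughters.
  // Returns daughter ids, or (0,0) if the split would leave a daughter empty.
  std::pair<int, int> divide_cell(int c, const std::vector<std::pair<int, int>>& px,
                                  double nx, double ny) {
    double cx = sumx[c] / vol[c], cy = sumy[c] / vol[c];
    int da = next_id++, db = next_id++;
    ensure_capacity(next_id + 64);
    int va = 0, vb = 0, alt = 0;
    for (auto& p : px) {
      double d = (p.first - cx) * nx + (p.second - cy) * ny;
      int who;
      if (d < -1e-9) who = da;
      else if (d > 1e-9) who = db;
      else who = (alt++ % 2 == 0) ? da : db;
      owner[idx(p.first, p.second)] = who;
      if (who == da) va++; else vb++;
    }
    if (va == 0 || vb == 0) {
      // degenerate geometry: undo, retry at a later MCS
      for (auto& p : px) owner[idx(p.first, p.second)] = c;
      next_id -= 2;
      return {0, 0};
    }
    int ptype = ctype_[c];
    for (int d2 : {da, db}) {
      ctype_[d2] = ptype; alive[d2] = 1; dying[d2] = 0; age_[d2] = 0;
      parent_[d2] = c; anchored[d2] = 0;
    }
    tvol[da] = va; tvol[db] = vb;
    alive[c] = 0;
    log_event(EV_DIVISION, c, da, db);
    return {da, db};
  }

  void mitosis(RunRNG& rng) {
    std::vector<int> dividing;
    for (int c = 1; c < next_id; ++c)
      if (alive[c] && !dying[c] && vol[c] >= mitosis_volume &&
          (ctype_[c] == T_STEM || ctype_[c] == T_BASAL))
        dividing.push_back(c);
    if (dividing.empty()) return;
    std::vector<int> mark(next_id, -1);
    for (size_t i = 0; i < dividing.size(); ++i) mark[dividing[i]] = (int)i;
    std::vector<std::vector<std::pair<int, int>>> pixels(dividing.size());
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int o = owner[idx(x, y)];
        if (o > 0 && o < (int)mark.size() && mark[o] >= 0)
          pixels[mark[o]].push_back({x, y});
      }
    for (size_t i = 0; i < dividing.size(); ++i) {
      int c = dividing[i];
      double nx, ny;
      if (ctype_[c] == T_STEM) {
        // centripetal: daughters separate along the x axis
        nx = 1.0; ny = 0.0;
      } else {
        double th = 2.0 * M_PI * rng.unif();
        nx = std::cos(th); ny = std::sin(th);
      }
      divide_cell(c, pixels[i], nx, ny);
    }
    recompute(true);
  }

  void slough(RunRNG& rng) {
    if (tear_id < 0) return;  // no tear compartment to shed into
    // tear contact from a fresh mini-sweep (mitosis may have changed ids)
    std::vector<signed char> contact(next_id, 0);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        int o = owner[idx(x, y)];
        if (o == 0 || ctype_[o] != T_SUPER) continue;
        for (int k = 0; k < 8; ++k) {
          int nx = x + DX8[k], ny = y + DY8[k];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          int n = owner[idx(nx, ny)];
          if (n != o && ct(n) == T_TEAR) { contact[o] = 1; break; }
        }
      }
    std::vector<signed char> gone(next_id, 0);
    bool any = false;
    for (int c = 1; c < next_id; ++c) {
      if (!alive[c] || ctype_[c] != T_SUPER || !contact[c]) continue;
      if (rng.unif() < slough_prob) {
        gone[c] = 1; any = true;
        log_event(EV_SLOUGH, c, sumx[c] / vol[c], sumy[c] / vol[c]);
      }
    }
    if (!any) return;
    for (int i = 0; i < W * H; ++i) {
      int o = owner[i];
      if (o > 0 && gone[o]) owner[i] = tear_id;
    }
    for (int c = 1; c < next_id; ++c)
      if (gone[c]) alive[c] = 0;
    recompute(false);
  }

  // Tear film maintenance: the tear compartment is re-formed every MCS as a
  // fixed-thickness layer over the current epithelial surface (increased
  // tear production fills vacated space); tear trapped inside the tissue is
  // left in place.
  void rewet() {
    if (tear_id < 0) return;
    for (int x = 0; x < W; ++x) {
      int ytop = -1;
      for (int y = H - 1; y >= 0; --y)
        if (type_is_solid(ct(owner[idx(x, y)]))) { ytop = y; break; }
      if (ytop < 0) continue;  // wall column
      // air trapped below the surface (under overhangs) becomes tear too
      for (int y = 0; y < ytop; ++y)
        if (ct(owner[idx(x, y)]) == T_AIR) owner[idx(x, y)] = tear_id;
      for (int y = ytop + 1; y < H; ++y) {
        int o = owner[idx(x, y)];
        int t = ct(o);
        if (t == T_WALL) continue;
        if (y <= ytop + tear_thickness) {
          if (t == T_AIR) owner[idx(x, y)] = tear_id;
        } else if (t == T_TEAR) {
          owner[idx(x, y)] = 0;
        }
      }
    }
  }

  void update_anchors() {
    if (lam_link <= 0) return;
    int memb_y = -1;
    // anchor row: first row containing membrane
    for (int y = 0; y < H && memb_y < 0; ++y)
      for (int x = 0; x < W; ++x) {
        int t = ct(owner[idx(x, y)]);
        if (t == T_LIMB || t == T_MEMB) { memb_y = y; break; }
      }
    if (memb_y < 0) return;
    for (int c = 1; c < next_id; ++c) {
      if (!alive[c]) continue;
      int t = ctype_[c];
      if (t != T_STEM && t != T_BASAL) {
        if (anchored[c] == 1) anchored[c] = 0;
        continue;
      }
      if (anchored[c] == 0 && aepbm[c] > 0) {
        anchored[c] = 1;
        anchx[c] = sumx[c] / vol[c];
        anchy[c] = memb_y;
      } else if (anchored[c] == 1) {
        int axp = std::min(W - 1, std::max(0, (int)std::lround(anchx[c])));
        int tunder = ct(owner[idx(axp, memb_y)]);
        if (tunder != T_LIMB && tunder != T_MEMB) anchored[c] = 2;  // broken for good
      }
    }
  }

  void census_sample() {
    for (int c = 1; c < next_id; ++c) {
      if (!alive[c] || !type_is_epithelial(ctype_[c])) continue;
      cs_mcs.push_back(mcs); cs_id.push_back(c); cs_type.push_back(ctype_[c]);
      cs_x.push_back(sumx[c] / vol[c]); cs_y.push_back(sumy[c] / vol[c]);
      cs_vol.push_back(vol[c]);
      cs_egf.push_back(c < (int)egfavg.size() ? egfavg[c] : 0.0);
    }
  }

  void run(int n_mcs, RunRNG& rng, int sample_every, List enable) {
    bool e_fields = as<bool>(enable["fields"]);
    bool e_kill = as<bool>(enable["kill"]);
    bool e_growth = as<bool>(enable["growth"]);
    bool e_diff = as<bool>(enable["differentiation"]);
    bool e_mit = as<bool>(enable["mitosis"]);
    bool e_slough = as<bool>(enable["slough"]);
    bool e_metro = as<bool>(enable["metropolis"]);
    bool e_rewet = as<bool>(enable["rewet"]);
    if (sample_every > 0 && mcs % sample_every == 0) {
      rule_pass();
      census_sample();
    }
    for (int step = 0; step < n_mcs; ++step) {
      if (e_fields) step_fields();
      rule_pass();
      if (e_kill) chemical_kill();
      if (e_growth) growth();
      if (e_diff) differentiate();
      if (e_mit) mitosis(rng);
      if (e_slough) slough(rng);
      update_anchors();
      if (e_metro) metropolis_sweep(rng);
      if (e_rewet) rewet();
      recompute(true);
      for (int c = 1; c < next_id; ++c)
        if (alive[c] && type_is_epithelial(ctype_[c])) age_[c]++;
      mcs++;
      if (sample_every > 0 && mcs % sample_every == 0) census_sample();
      if (step % 256 == 0) Rcpp::checkUserInterrupt();
    }
  }

  List dump_state() const {
    IntegerMatrix og(W, H);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) og(x, y) = owner[idx(x, y)];
    int n = 0;
    for (int c = 1; c < next_id; ++c) if (alive[c]) n++;
    IntegerVector id(n), type(n), volv(n), surfv(n), agev(n), dyv(n), anv(n), pav(n);
    NumericVector tv(n), cx(n), cy(n), ax(n), ay(n);
    int i = 0;
    for (int c = 1; c < next_id; ++c) {
      if (!alive[c]) continue;
      id[i] = c; type[i] = ctype_[c]; volv[i] = vol[c]; surfv[i] = surf[c];
      tv[i] = tvol[c]; cx[i] = vol[c] > 0 ? sumx[c] / vol[c] : NA_REAL;
      cy[i] = vol[c] > 0 ? sumy[c] / vol[c] : NA_REAL;
      agev[i] = age_[c]; dyv[i] = dying[c]; anv[i] = anchored[c];
      ax[i] = anchx[c]; ay[i] = anchy[c]; pav[i] = parent_[c];
      i++;
    }
    List cells = List::create(
        _["id"] = id, _["type"] = type, _["volume"] = volv,
        _["target_volume"] = tv, _["surface"] = surfv, _["comx"] = cx,
        _["comy"] = cy, _["age"] = agev, _["dying"] = dyv,
        _["anchored"] = anv, _["anchor_x"] = ax, _["anchor_y"] = ay,
        _["parent"] = pav);
    NumericMatrix em(W, H), tm(W, H);
    for (int y = 0; y < H; ++y)
      for (int x = 0; x < W; ++x) {
        em(x, y) = egf[idx(x, y)];
        tm(x, y) = tox[idx(x, y)];
      }
    return List::create(_["owner"] = og, _["cells"] = cells, _["egf"] = em,
                        _["tox"] = tox_spec.on ? (RObject)tm : (RObject)R_NilValue,
                        _["mcs"] = mcs, _["next_id"] = next_id);
  }

  NumericMatrix dump_census() const {
    int n = (int)cs_mcs.size();
    NumericMatrix m(n, 7);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = cs_mcs[i]; m(i, 1) = cs_id[i]; m(i, 2) = cs_type[i];
      m(i, 3) = cs_x[i]; m(i, 4) = cs_y[i]; m(i, 5) = cs_vol[i];
      m(i, 6) = cs_egf[i];
    }
    colnames(m) = CharacterVector::create("mcs", "id", "type", "comx", "comy",
                                          "volume", "egf");
    return m;
  }

  NumericMatrix dump_events() const {
    int n = (int)ev_mcs.size();
    NumericMatrix m(n, 6);
    for (int i = 0; i < n; ++i) {
      m(i, 0) = ev_mcs[i]; m(i, 1) = ev_code[i]; m(i, 2) = ev_id[i];
      m(i, 3) = ev_a[i]; m(i, 4) = ev_b[i]; m(i, 5) = ev_type[i];
    }
    colnames(m) = CharacterVector::create("mcs", "code", "id", "a", "b", "type");
    return m;
  }
};

// ---- exported interface ---------------------------------------------------

// [[Rcpp::export]]
List cpp_run(List state, List potts, List rules, Nullable<List> egf_par,
             Nullable<List> tox_par, int n_mcs, int seed, int sample_every,
             List enable) {
  Engine e;
  e.load(state, potts, rules, egf_par, tox_par);
  RunRNG rng(static_cast<uint64_t>(seed));
  e.run(n_mcs, rng, sample_every, enable);
  IntegerVector kbt(NTYPES);
  for (int t = 0; t < NTYPES; ++t) kbt[t] = e.killed_by_type[t];
  return List::create(
      _["state"] = e.dump_state(), _["census"] = e.dump_census(),
      _["events"] = e.dump_events(), _["attempts"] = (double)e.attempts,
      _["accepts"] = (double)e.accepts, _["killed_by_type"] = kbt,
      _["memb_destroyed"] = e.memb_destroyed);
}

// Volume-triggered division of one named cell: splits its pixel set by a
// cleavage line through the COM (stem cells: normal along x, so daughters
// separate centripetally; basal cells: uniformly random orientation).
// Returns NULL daughters if the cell is below the mitosis volume.
// [[Rcpp::export]]
List cpp_divide(List state, List potts, List rules, int cell_id, int seed) {
  Engine e;
  e.load(state, potts, rules, R_NilValue, R_NilValue);
  if (cell_id <= 0 || cell_id >= e.next_id || !e.alive[cell_id])
    stop("cell not found");
  int t = e.ctype_[cell_id];
  if (t != T_STEM && t != T_BASAL)
    stop("only stem and basal cells divide");
  if (e.vol[cell_id] < e.mitosis_volume || e.dying[cell_id])
    return List::create(_["state"] = e.dump_state(),
                        _["daughters"] = R_NilValue);
  std::vector<std::pair<int, int>> px;
  for (int y = 0; y < e.H; ++y)
    for (int x = 0; x < e.W; ++x)
      if (e.owner[e.idx(x, y)] == cell_id) px.push_back({x, y});
  RunRNG rng(static_cast<uint64_t>(seed));
  double nx = 1.0, ny = 0.0;
  if (t == T_BASAL) {
    double th = 2.0 * M_PI * rng.unif();
    nx = std::cos(th);
    ny = std::sin(th);
  }
  auto d = e.divide_cell(cell_id, px, nx, ny);
  e.recompute(false);
  RObject daughters = R_NilValue;
  if (d.first > 0) daughters = IntegerVector::create(d.first, d.second);
  return List::create(_["state"] = e.dump_state(), _["daughters"] = daughters);
}

// Repeated draws of the Metropolis acceptance decision at a fixed energy
// change, for statistical validation of the acceptance rule.
// [[Rcpp::export]]
int cpp_accept_trials(double dH, double temperature, int n, int seed) {
  RunRNG rng(static_cast<uint64_t>(seed));
  int acc = 0;
  for (int i = 0; i < n; ++i)
    if (metropolis_accept(dH, temperature, rng)) acc++;
  return acc;
}

// Incremental energy change for a single hypothetical pixel copy.
// [[Rcpp::export]]
double cpp_delta_h(List state, List potts, List rules, Nullable<List> egf_par,
                   IntegerVector source_px, IntegerVector target_px) {
  Engine e;
  e.load(state, potts, rules, egf_par, R_NilValue);
  int px = source_px[0], py = source_px[1], qx = target_px[0], qy = target_px[1];
  if (px < 0 || px >= e.W || py < 0 || py >= e.H || qx < 0 || qx >= e.W ||
      qy < 0 || qy >= e.H)
    stop("pixel out of bounds");
  int dx = std::abs(px - qx), dy2 = std::abs(py - qy);
  if (dx > 1 || dy2 > 1 || (dx == 0 && dy2 == 0))
    stop("source and target must be lattice neighbours");
  int s = e.owner[e.idx(px, py)], t = e.owner[e.idx(qx, qy)];
  if (s == t) stop("source and target owners are identical");
  if (type_is_frozen(e.ct(s)) || type_is_frozen(e.ct(t)) || e.ct(s) == T_AIR ||
      e.ct(t) == T_AIR)
    stop("copy attempts involving frozen or medium pixels are rejected");
  return e.delta_h(px, py, qx, qy, nullptr, nullptr);
}

// Full-rescan bookkeeping oracle: per-cell volume, boundary-face count and
// COM recomputed from the owner grid alone.
// [[Rcpp::export]]
List cpp_rescan(IntegerMatrix owner) {
  int W = owner.nrow(), H = owner.ncol();
  std::map<int, std::array<double, 4>> acc;  // id -> vol, surf, sx, sy
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      int o = owner(x, y);
      if (o == 0) continue;
      auto& a = acc[o];
      a[0] += 1; a[2] += x; a[3] += y;
      for (int k = 0; k < 4; ++k) {
        int nx = x + DX4[k], ny = y + DY4[k];
        if (nx < 0 || nx >= W || ny < 0 || ny >= H || owner(nx, ny) != o)
          a[1] += 1;
      }
    }
  int n = (int)acc.size();
  IntegerVector id(n), volv(n), surfv(n);
  NumericVector cx(n), cy(n);
  int i = 0;
  for (auto& kv : acc) {
    id[i] = kv.first; volv[i] = (int)kv.second[0]; surfv[i] = (int)kv.second[1];
    cx[i] = kv.second[2] / kv.second[0]; cy[i] = kv.second[3] / kv.second[0];
    i++;
  }
  return List::create(_["id"] = id, _["volume"] = volv, _["surface"] = surfv,
                      _["comx"] = cx, _["comy"] = cy);
}

// Connectivity diagnostic: number of cells whose pixel set is not
// 8-connected (fragmentation is monitored, not forbidden).
// [[Rcpp::export]]
int cpp_count_fragmented(IntegerMatrix owner) {
  int W = owner.nrow(), H = owner.ncol();
  std::vector<signed char> seen(W * H, 0);
  std::map<int, int> components;
  for (int y0 = 0; y0 < H; ++y0)
    for (int x0 = 0; x0 < W; ++x0) {
      int o = owner(x0, y0);
      if (o <= 0 || seen[x0 + y0 * W]) continue;
      components[o]++;
      std::vector<std::pair<int, int>> stack = {{x0, y0}};
      seen[x0 + y0 * W] = 1;
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (int k = 0; k < 8; ++k) {
          int nx = p.first + DX8[k], ny = p.second + DY8[k];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          if (owner(nx, ny) == o && !seen[nx + ny * W]) {
            seen[nx + ny * W] = 1;
            stack.push_back({nx, ny});
          }
        }
      }
    }
  int frag = 0;
  for (auto& kv : components)
    if (kv.second > 1) frag++;
  return frag;
}
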