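// Hourly land-surface core: surface energy balance, implicit 1-D heat
// conduction through an (optional snow) -> (optional residue) -> 11-layer
// soil stack with apparent-heat-capacity freezing, bulk snowpack mass
// balance, and a field-capacity bucket for soil water.
//
// The R-level module functions are thin wrappers over the step functions
// exported here, so the engine and the user-facing operations share one
// implementation.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double L_F    = 334000.0;     // latent heat of fusion, J kg-1
static const double RHO_W  = 1000.0;       // liquid water density, kg m-3
static const double C_W    = 4.18e6;       // liquid water volumetric heat capacity, J m-3 K-1
static const double C_I    = 1.9e6;        // ice volumetric heat capacity, J m-3 K-1
static const double C_AIR  = 1212.0;       // air volumetric heat capacity, J m-3 K-1
static const double CP_ICE = 2100.0;       // ice specific heat, J kg-1 K-1
static const double SIGMA  = 5.670374419e-8;
static const double KARMAN = 0.4;
static const double RHO_A  = 1.225;        // air density, kg m-3
static const double CP_A   = 1005.0;       // air specific heat, J kg-1 K-1
static const double L_V    = 2.501e6;      // latent heat of vaporization, J kg-1
static const double P_ATM  = 101325.0;

// ---------------------------------------------------------------------------
// helpers

static inline double esat_pa(double t_c) {
  return 611.0 * std::exp(17.27 * t_c / (t_c + 237.3));
}
static inline double spec_hum(double e_pa) {
  return 0.622 * e_pa / (P_ATM - 0.378 * e_pa);
}

// equilibrium liquid fraction of freezable water over the freezing range
static inline double liquid_frac(double t_c, double dTf) {
  if (t_c >= 0.0) return 1.0;
  if (t_c <= -dTf) return 0.0;
  return 1.0 + t_c / dTf;
}

// enthalpy per unit area (J m-2) of a soil layer relative to
// (liquid water at 0 C); c_base = solids + air sensible capacity, J m-3 K-1
static double soil_enthalpy(double t_c, double theta, double c_base,
                            double dz, double dTf) {
  double lf = liquid_frac(t_c, dTf);
  double c_sens = c_base + C_W * theta * lf + C_I * theta * (1.0 - lf);
  return c_sens * dz * t_c + L_F * RHO_W * theta * dz * (lf - 1.0);
}

// invert soil_enthalpy by bisection (E is strictly increasing in T)
static double soil_temp_from_enthalpy(double e, double theta, double c_base,
                                      double dz, double dTf) {
  double e0 = soil_enthalpy(0.0, theta, c_base, dz, dTf);          // all liquid
  if (e >= e0) {
    double c_u = c_base + C_W * theta;
    return (e - e0) / (c_u * dz);
  }
  double e1 = soil_enthalpy(-dTf, theta, c_base, dz, dTf);         // all ice
  if (e <= e1) {
    double c_f = c_base + C_I * theta;
    return -dTf + (e - e1) / (c_f * dz);
  }
  double lo = -dTf, hi = 0.0;
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    if (soil_enthalpy(mid, theta, c_base, dz, dTf) < e) lo = mid; else hi = mid;
    if (hi - lo < 1e-13) break;
  }
  return 0.5 * (lo + hi);
}

// Thomas algorithm, overwrites inputs
static void thomas(std::vector<double>& a, std::vector<double>& b,
                   std::vector<double>& c, std::vector<double>& d,
                   std::vector<double>& x) {
  int n = b.size();
  for (int i = 1; i < n; ++i) {
    double m = a[i] / b[i - 1];
    b[i] -= m * c[i - 1];
    d[i] -= m * d[i - 1];
  }
  x[n - 1] = d[n - 1] / b[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = (d[i] - c[i] * x[i + 1]) / b[i];
}

// ---------------------------------------------------------------------------
// single-layer energy application (freeze/thaw partition)

// [[Rcpp::export]]
List cpp_apply_energy_layer(double temp, double liquid, double ice,
                            double energy, double c_base, double dz,
                            double dTf) {
  double theta = liquid + ice;
  double c_sens = c_base + C_W * liquid + C_I * ice;
  double e_old = c_sens * dz * temp - L_F * RHO_W * ice * dz;
  double e_new = e_old + energy;
  double t_new, liq_new, ice_new;
  if (theta <= 0.0) {
    t_new = temp + energy / (c_base * dz);
    liq_new = 0.0; ice_new = 0.0;
  } else {
    t_new = soil_temp_from_enthalpy(e_new, theta, c_base, dz, dTf);
    double lf = liquid_frac(t_new, dTf);
    liq_new = theta * lf;
    ice_new = theta - liq_new;
  }
  return List::create(_["temp"] = t_new, _["liquid"] = liq_new,
                      _["ice"] = ice_new);
}

// ---------------------------------------------------------------------------
// implicit conduction step over an arbitrary slab stack
//
// top_mode: 0 = prescribed flux (flux_top, W m-2, positive downward)
//           1 = Dirichlet skin temperature t_top
// bot_mode: 0 = zero flux, 1 = Dirichlet t_bot
// is_soil slabs carry freezable water theta and use enthalpy accounting.

// [[Rcpp::export]]
List cpp_step_conduction(NumericVector thick, NumericVector kcond,
                         NumericVector c_base, NumericVector temp,
                         LogicalVector is_soil, NumericVector theta,
                         double dt, double dTf,
                         int top_mode, double flux_top, double t_top,
                         int bot_mode, double t_bot) {
  int n = thick.size();
  std::vector<double> t_old(n), t_it(n), e_old(n);
  for (int i = 0; i < n; ++i) {
    t_old[i] = temp[i];
    t_it[i] = temp[i];
    e_old[i] = is_soil[i]
      ? soil_enthalpy(temp[i], theta[i], c_base[i], thick[i], dTf)
      : c_base[i] * thick[i] * temp[i];
  }
  // interface conductances (harmonic / series of half-slabs)
  std::vector<double> g(n - 1 > 0 ? n - 1 : 0);
  for (int i = 0; i + 1 < n; ++i)
    g[i] = 1.0 / (0.5 * thick[i] / kcond[i] + 0.5 * thick[i + 1] / kcond[i + 1]);
  double g_top = kcond[0] / (0.5 * thick[0]);
  double g_bot = kcond[n - 1] / (0.5 * thick[n - 1]);

  std::vector<double> a(n), b(n), c(n), d(n), t_new(n);
  std::vector<double> ceff(n), t_sol(n), ceff_sol(n);
  int iter = 0;
  for (iter = 0; iter < 80; ++iter) {
    // effective (secant) capacities at the current iterate
    for (int i = 0; i < n; ++i) {
      if (!is_soil[i]) { ceff[i] = c_base[i]; continue; }
      double dtt = t_it[i] - t_old[i];
      if (std::fabs(dtt) > 1e-9) {
        double e_it = soil_enthalpy(t_it[i], theta[i], c_base[i], thick[i], dTf);
        ceff[i] = (e_it - e_old[i]) / dtt / thick[i];
      } else {
        // pointwise dE/dT
        double lf = liquid_frac(t_it[i], dTf);
        double cs = c_base[i] + C_W * theta[i] * lf + C_I * theta[i] * (1.0 - lf);
        if (t_it[i] > -dTf && t_it[i] < 0.0)
          cs += (L_F * RHO_W * theta[i] +
                 (C_W - C_I) * theta[i] * t_it[i]) / dTf;
        ceff[i] = cs;
      }
      if (ceff[i] < 1e3) ceff[i] = 1e3;
    }
    for (int i = 0; i < n; ++i) {
      double cap = ceff[i] * thick[i] / dt;
      a[i] = 0.0; b[i] = cap; c[i] = 0.0; d[i] = cap * t_old[i];
      if (i > 0)     { a[i] = -g[i - 1]; b[i] += g[i - 1]; }
      if (i + 1 < n) { c[i] = -g[i];     b[i] += g[i]; }
    }
    if (top_mode == 0) d[0] += flux_top;
    else { b[0] += g_top; d[0] += g_top * t_top; }
    if (bot_mode == 1) { b[n - 1] += g_bot; d[n - 1] += g_bot * t_bot; }
    thomas(a, b, c, d, t_new);
    t_sol = t_new; ceff_sol = ceff;   // latest consistent (solve, capacity) pair
    double max_dt_iter = 0.0;
    for (int i = 0; i < n; ++i)
      max_dt_iter = std::max(max_dt_iter, std::fabs(t_new[i] - t_it[i]));
    if (max_dt_iter < 1e-7) { t_it = t_new; break; }
    // damped update after initial sweeps to avoid phase-boundary cycling
    double w = (iter < 15) ? 1.0 : 0.6;
    for (int i = 0; i < n; ++i) t_it[i] = w * t_new[i] + (1.0 - w) * t_it[i];
  }
  // conservative projection: the linear solve moves energy
  // ceff_i*dz_i*(t_sol_i - t_old_i) per slab (telescoping exactly to the
  // boundary fluxes); invert the enthalpy actually received so the final
  // state conserves energy regardless of Picard convergence quality.
  NumericVector t_out(n), liq_frac_out(n);
  double de_stored = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!R_finite(t_sol[i]))
      stop("non-finite temperature in conduction step (slab %d)", i + 1);
    double e_new = e_old[i] + ceff_sol[i] * thick[i] * (t_sol[i] - t_old[i]);
    de_stored += e_new - e_old[i];
    if (is_soil[i]) {
      double ts = soil_temp_from_enthalpy(e_new, theta[i], c_base[i],
                                          thick[i], dTf);
      t_out[i] = ts;
      liq_frac_out[i] = liquid_frac(ts, dTf);
    } else {
      t_out[i] = e_new / (c_base[i] * thick[i]);
      liq_frac_out[i] = 1.0;
    }
  }
  double q_top = (top_mode == 0) ? flux_top : g_top * (t_top - t_sol[0]);
  double q_bot = (bot_mode == 1) ? g_bot * (t_sol[n - 1] - t_bot) : 0.0;
  return List::create(_["temp"] = t_out, _["liquid_fraction"] = liq_frac_out,
                      _["flux_top"] = q_top, _["flux_bottom"] = q_bot,
                      _["energy_change"] = de_stored,
                      _["closure_error"] = de_stored - (q_top - q_bot) * dt,
                      _["iterations"] = iter + 1);
}

// ---------------------------------------------------------------------------
// surface energy balance: solve skin temperature by bisection

// [[Rcpp::export]]
List cpp_surface_energy_balance(double sw, double lwd, double tair, double rh,
                                double wind, double albedo, double z0,
                                double emiss, double g_cond, double t_below,
                                bool latent_on, double beta, double zref) {
  if (albedo <= 0.0 || albedo >= 1.0) stop("albedo must be in (0,1)");
  if (wind < 0.0) stop("wind must be >= 0");
  double ch = KARMAN * KARMAN / std::pow(std::log(zref / z0), 2.0);
  double ueff = std::max(wind, 0.1);
  double hcoef = RHO_A * CP_A * ch * ueff;
  double qa = spec_hum(rh / 100.0 * esat_pa(tair));
  double net_sw = (1.0 - albedo) * sw;

  auto resid = [&](double ts) {
    double tk = ts + 273.15;
    double net_lw = emiss * (lwd - SIGMA * tk * tk * tk * tk);
    double h = hcoef * (ts - tair);
    double le = 0.0;
    if (latent_on) {
      le = beta * RHO_A * L_V * ch * ueff * (spec_hum(esat_pa(ts)) - qa);
      if (le < 0.0) le = 0.0;
    }
    double gflux = g_cond * (ts - t_below);
    return net_sw + net_lw - h - le - gflux;
  };

  double lo = tair - 60.0, hi = tair + 60.0;
  double flo = resid(lo), fhi = resid(hi);
  int guard = 0;
  while (flo < 0.0 && guard++ < 5) { lo -= 40.0; flo = resid(lo); }
  guard = 0;
  while (fhi > 0.0 && guard++ < 5) { hi += 40.0; fhi = resid(hi); }
  if (flo < 0.0 || fhi > 0.0)
    stop("surface energy balance failed to bracket a solution");
  double ts = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    ts = 0.5 * (lo + hi);
    double f = resid(ts);
    if (std::fabs(f) < 1e-6) break;
    if (f > 0.0) lo = ts; else hi = ts;
  }
  double tk = ts + 273.15;
  double net_lw = emiss * (lwd - SIGMA * tk * tk * tk * tk);
  double h = hcoef * (ts - tair);
  double le = 0.0;
  if (latent_on) {
    le = beta * RHO_A * L_V * ch * ueff * (spec_hum(esat_pa(ts)) - qa);
    if (le < 0.0) le = 0.0;
  }
  double gflux = g_cond * (ts - t_below);
  return List::create(_["skin_temp"] = ts, _["net_shortwave"] = net_sw,
                      _["net_longwave"] = net_lw, _["sensible"] = h,
                      _["latent"] = le, _["ground_heat_flux"] = gflux,
                      _["residual"] = net_sw + net_lw - h - le - gflux);
}

// ---------------------------------------------------------------------------
// field-capacity cascade bucket; dz in m, water contents volumetric

// [[Rcpp::export]]
List cpp_bucket_update(NumericVector liquid, NumericVector ice,
                       NumericVector dz, NumericVector porosity,
                       NumericVector field_capacity,
                       NumericVector wilting_point,
                       double infiltration_mm, double evap_mm) {
  if (infiltration_mm < 0.0 || evap_mm < 0.0)
    stop("infiltration and evaporation must be >= 0");
  int n = liquid.size();
  NumericVector liq = clone(liquid);
  double storage0 = 0.0;
  for (int i = 0; i < n; ++i) storage0 += (liq[i] + ice[i]) * dz[i] * 1000.0;

  // evaporation from the top layer, floored at the wilting point
  double evap_act = 0.0;
  if (evap_mm > 0.0 && ice[0] <= 1e-12) {
    double avail = (liq[0] - wilting_point[0]) * dz[0] * 1000.0;
    if (avail < 0.0) avail = 0.0;
    evap_act = std::min(evap_mm, avail);
    liq[0] -= evap_act / (dz[0] * 1000.0);
  }

  // infiltration cascade: fill to field capacity (capped by air-filled
  // porosity), excess moves down; frozen layers accept no infiltration
  double water = infiltration_mm;
  double runoff = 0.0, drainage = 0.0;
  if (ice[0] > 1e-12) {
    runoff = water; water = 0.0;
  }
  for (int i = 0; i < n && water > 0.0; ++i) {
    if (ice[i] > 1e-12) { runoff += water; water = 0.0; break; }
    double cap_theta = std::min(field_capacity[i], porosity[i] - ice[i]);
    double room = (cap_theta - liq[i]) * dz[i] * 1000.0;
    if (room < 0.0) room = 0.0;
    double add = std::min(water, room);
    liq[i] += add / (dz[i] * 1000.0);
    water -= add;
  }
  drainage = water;  // past the bottom of the column

  double storage1 = 0.0;
  for (int i = 0; i < n; ++i) storage1 += (liq[i] + ice[i]) * dz[i] * 1000.0;
  double closure = (storage1 - storage0) -
                   (infiltration_mm - runoff - evap_act - drainage);
  return List::create(_["liquid"] = liq, _["evap_actual"] = evap_act,
                      _["drainage"] = drainage, _["runoff"] = runoff,
                      _["storage_change_mm"] = storage1 - storage0,
                      _["closure_error_mm"] = closure);
}

// ---------------------------------------------------------------------------
// Johansen-style soil thermal conductivity + volumetric heat capacity

// [[Rcpp::export]]
List cpp_soil_thermal_properties(double liquid, double ice, double porosity,
                                 double k_dry, double k_solids,
                                 double c_solids) {
  if (liquid < 0.0 || ice < 0.0) stop("negative water contents");
  double theta = liquid + ice;
  if (theta > porosity + 1e-9) stop("liquid + ice exceeds porosity");
  const double K_W = 0.57, K_ICE = 2.2;
  double k;
  if (theta <= 1e-12) {
    k = k_dry;
  } else {
    double fl = liquid / theta;
    double sr = std::min(1.0, theta / porosity);
    double k_sat = std::pow(k_solids, 1.0 - porosity) *
                   std::pow(K_W, porosity * fl) *
                   std::pow(K_ICE, porosity * (1.0 - fl));
    double ke_u = (sr > 0.1) ? (std::log10(sr) + 1.0) : 0.0;
    double ke_f = sr;
    double ke = fl * ke_u + (1.0 - fl) * ke_f;
    k = k_dry + ke * (k_sat - k_dry);
    if (k < k_dry) k = k_dry;
  }
  double cvol = c_solids * (1.0 - porosity) + C_W * liquid + C_I * ice +
                C_AIR * (porosity - theta);
  return List::create(_["conductivity"] = k, _["heat_capacity"] = cvol);
}

// snow conductivity from density, Yen (1981)
// [[Rcpp::export]]
double cpp_snow_conductivity(double rho_snow) {
  return 2.22362 * std::pow(rho_snow / 1000.0, 1.885);
}

// ---------------------------------------------------------------------------
// full column run
//
// forc: n_hours x 7 matrix [tair, precip_mm, is_snow, sw, lwd, rh, wind]
// soil: list of 11-vectors (thick_m, porosity, field_capacity, wilting_point,
//       k_dry, k_solids, c_solids) + init (temp, liquid, ice)
// surf: list(res_present, res_thick, res_k, res_cvol, res_albedo, res_z0,
//            snow_rho, snow_albedo, snow_dfull, snow_min_swe,
//            soil_albedo, soil_z0)
// opts: list(dt_s, emiss, dTf, zref, probe_depth_cm)

// [[Rcpp::export]]
List cpp_run_column(NumericMatrix forc, List soil, List surf, List opts) {
  NumericVector s_thick = soil["thick_m"], s_por = soil["porosity"],
                s_fc = soil["field_capacity"], s_wp = soil["wilting_point"],
                s_kdry = soil["k_dry"], s_ksol = soil["k_solids"],
                s_csol = soil["c_solids"];
  NumericVector t_soil = clone(as<NumericVector>(soil["init_temp"]));
  NumericVector liq = clone(as<NumericVector>(soil["init_liquid"]));
  NumericVector ice = clone(as<NumericVector>(soil["init_ice"]));
  int ns = s_thick.size();

  bool res_present = as<bool>(surf["res_present"]);
  double res_thick = as<double>(surf["res_thick"]);
  double res_k = as<double>(surf["res_k"]);
  double res_cvol = as<double>(surf["res_cvol"]);
  double res_albedo = as<double>(surf["res_albedo"]);
  double res_z0 = as<double>(surf["res_z0"]);
  double snow_rho = as<double>(surf["snow_rho"]);
  double snow_albedo = as<double>(surf["snow_albedo"]);
  double snow_dfull = as<double>(surf["snow_dfull"]);
  double snow_min_swe = as<double>(surf["snow_min_swe"]);
  double soil_albedo = as<double>(surf["soil_albedo"]);
  double soil_z0 = as<double>(surf["soil_z0"]);
  if (res_present && res_thick <= 0.0) res_present = false;

  double dt = as<double>(opts["dt_s"]);
  double emiss = as<double>(opts["emiss"]);
  double dTf = as<double>(opts["dTf"]);
  double zref = as<double>(opts["zref"]);
  double probe = as<double>(opts["probe_depth_cm"]);

  int nh = forc.nrow();
  int steps_per_day = (int)std::lround(86400.0 / dt);
  int nd = nh / steps_per_day;

  double k_snow = cpp_snow_conductivity(snow_rho);
  double c_snow_vol = snow_rho * CP_ICE;

  // soil node depths (cm) for probe interpolation
  std::vector<double> node_cm(ns);
  {
    double z = 0.0;
    for (int i = 0; i < ns; ++i) {
      node_cm[i] = (z + 0.5 * s_thick[i]) * 100.0;
      z += s_thick[i];
    }
  }
  auto probe_temp = [&](void) {
    if (probe <= node_cm[0]) return (double)t_soil[0];
    for (int i = 0; i + 1 < ns; ++i)
      if (probe <= node_cm[i + 1]) {
        double w = (probe - node_cm[i]) / (node_cm[i + 1] - node_cm[i]);
        return t_soil[i] * (1.0 - w) + t_soil[i + 1] * w;
      }
    return (double)t_soil[ns - 1];
  };

  // snow state
  double swe = 0.0, t_snow = 0.0;

  // ledgers
  double cum_G = 0.0, cum_absG = 0.0, cum_adv = 0.0, cum_ext = 0.0;
  double cum_melt_out = 0.0;            // enthalpy of melt water leaving (=0 ref)
  double solver_closure = 0.0;
  double cum_snowfall = 0.0, cum_melt = 0.0, swe_residual_max = 0.0;
  double cum_infil = 0.0, cum_evap = 0.0, cum_drain = 0.0, cum_runoff = 0.0;
  double water_closure_max = 0.0;

  auto stack_energy = [&](void) {
    double e = 0.0;
    for (int i = 0; i < ns; ++i) {
      double th = liq[i] + ice[i];
      double cb = s_csol[i] * (1.0 - s_por[i]) + C_AIR * (s_por[i] - th);
      double cs = cb + C_W * liq[i] + C_I * ice[i];
      e += cs * s_thick[i] * t_soil[i] - L_F * RHO_W * ice[i] * s_thick[i];
    }
    if (swe > 0.0) e += swe * (CP_ICE * t_snow - L_F);  // swe in kg m-2 == mm
    if (res_present) e += res_cvol * res_thick * 0.0;   // residue tracked below
    return e;
  };
  double t_res = t_soil[0];  // residue slab temperature state
  auto res_energy = [&](void) {
    return res_present ? res_cvol * res_thick * t_res : 0.0;
  };
  double e_start = stack_energy() + res_energy();

  // daily accumulators
  NumericVector out_t10(nd), out_snowdepth(nd), out_swe(nd), out_albedo(nd),
                out_tskin_min(nd);
  double acc_t10 = 0.0, acc_depth = 0.0, acc_alb = 0.0, tskin_min = 1e9;
  double pool_infil = 0.0, pool_evap = 0.0;
  int day = 0, step_in_day = 0;

  // scratch stack arrays (snow + residue + soil)
  int nmax = ns + 2;
  NumericVector st_thick(nmax), st_k(nmax), st_cb(nmax), st_T(nmax),
                st_theta(nmax);
  LogicalVector st_soil(nmax);

  for (int h = 0; h < nd * steps_per_day; ++h) {
    double tair = forc(h, 0), pmm = forc(h, 1);
    bool psnow = forc(h, 2) > 0.5;
    double sw = forc(h, 3), lwd = forc(h, 4), rh = forc(h, 5),
           wind = forc(h, 6);

    // precipitation handling
    if (pmm > 0.0) {
      if (psnow) {
        double tnew = std::min(tair, 0.0);
        cum_adv += pmm * (CP_ICE * tnew - L_F);
        t_snow = (swe + pmm > 0.0)
                   ? (swe * t_snow + pmm * tnew) / (swe + pmm) : 0.0;
        swe += pmm;
        cum_snowfall += pmm;
      } else {
        pool_infil += pmm;  // rain (passes through any snowpack)
      }
    }

    bool snow_slab = swe >= snow_min_swe;
    double snow_depth = swe / snow_rho;  // swe mm == kg m-2; depth m
    // thin pack: negligible thermal mass, keep at min(tair,0); melts if warm
    if (!snow_slab && swe > 0.0) {
      double e_pre = swe * (CP_ICE * t_snow - L_F);
      if (tair > 0.0) {
        pool_infil += swe; cum_melt += swe; swe = 0.0; t_snow = 0.0;
        cum_ext += 0.0 - e_pre;  // external energy supplied the melt
      } else {
        t_snow = std::min(tair, 0.0);
        cum_ext += swe * (CP_ICE * t_snow - L_F) - e_pre;
      }
      snow_depth = swe / snow_rho;
    }

    // assemble stack
    int n = 0;
    if (snow_slab) {
      st_thick[n] = std::max(snow_depth, 0.005);
      st_k[n] = k_snow; st_cb[n] = c_snow_vol; st_T[n] = t_snow;
      st_soil[n] = false; st_theta[n] = 0.0; ++n;
    }
    int i_res = -1;
    if (res_present) {
      i_res = n;
      st_thick[n] = res_thick; st_k[n] = res_k; st_cb[n] = res_cvol;
      st_T[n] = t_res; st_soil[n] = false; st_theta[n] = 0.0; ++n;
    }
    int i_soil0 = n;
    for (int i = 0; i < ns; ++i, ++n) {
      double th = liq[i] + ice[i];
      List tp = cpp_soil_thermal_properties(liq[i], ice[i], s_por[i],
                                            s_kdry[i], s_ksol[i], s_csol[i]);
      st_thick[n] = s_thick[i];
      st_k[n] = as<double>(tp["conductivity"]);
      st_cb[n] = s_csol[i] * (1.0 - s_por[i]) + C_AIR * (s_por[i] - th);
      st_T[n] = t_soil[i];
      st_soil[n] = true; st_theta[n] = th;
    }

    // albedo and surface properties
    double fsnow = std::min(1.0, snow_depth / snow_dfull);
    double ground_alb = res_present ? res_albedo : soil_albedo;
    double alb = fsnow * snow_albedo + (1.0 - fsnow) * ground_alb;
    double z0 = snow_slab ? 0.002 : (res_present ? res_z0 : soil_z0);
    bool latent_on = !snow_slab && !res_present && ice[0] <= 1e-12;
    double beta = latent_on
      ? std::max(0.0, std::min(1.0, (liq[0] - s_wp[0]) / (s_fc[0] - s_wp[0])))
      : 0.0;

    double g_top = st_k[0] / (0.5 * st_thick[0]);
    List seb = cpp_surface_energy_balance(sw, lwd, tair, rh, wind, alb, z0,
                                          emiss, g_top, st_T[0], latent_on,
                                          beta, zref);
    double G = as<double>(seb["ground_heat_flux"]);
    double le = as<double>(seb["latent"]);
    double tskin = as<double>(seb["skin_temp"]);
    pool_evap += le * dt / (L_V * RHO_W) * 1000.0;  // mm

    // conduction
    NumericVector vthick(st_thick.begin(), st_thick.begin() + n);
    NumericVector vk(st_k.begin(), st_k.begin() + n);
    NumericVector vcb(st_cb.begin(), st_cb.begin() + n);
    NumericVector vT(st_T.begin(), st_T.begin() + n);
    NumericVector vtheta(st_theta.begin(), st_theta.begin() + n);
    LogicalVector vsoil(st_soil.begin(), st_soil.begin() + n);
    List cond = cpp_step_conduction(vthick, vk, vcb, vT, vsoil, vtheta,
                                    dt, dTf, 0, G, 0.0, 0, 0.0);
    NumericVector t_new = cond["temp"];
    NumericVector lf_new = cond["liquid_fraction"];
    solver_closure += std::fabs(as<double>(cond["closure_error"]));
    cum_G += G * dt; cum_absG += std::fabs(G) * dt;

    // unpack stack
    int idx = 0;
    if (snow_slab) { t_snow = t_new[idx]; ++idx; }
    if (res_present) { t_res = t_new[idx]; ++idx; }
    for (int i = 0; i < ns; ++i) {
      t_soil[i] = t_new[idx + i];
      double th = liq[i] + ice[i];
      liq[i] = th * lf_new[idx + i];
      ice[i] = th - liq[i];
    }

    // snow melt: bulk temperature above 0 C melts at L_F
    if (snow_slab && t_snow > 0.0) {
      double cvol_dz = c_snow_vol * std::max(snow_depth, 0.005);
      double e_excess = cvol_dz * t_snow;
      double melt = e_excess / L_F;  // kg m-2 == mm
      if (melt >= swe) {
        double e_left = e_excess - swe * L_F;
        pool_infil += swe; cum_melt += swe; swe = 0.0; t_snow = 0.0;
        // leftover energy warms the slab below
        if (res_present) {
          t_res += e_left / (res_cvol * res_thick);
        } else {
          double th = liq[0] + ice[0];
          double cb = s_csol[0] * (1.0 - s_por[0]) + C_AIR * (s_por[0] - th);
          List ap = cpp_apply_energy_layer(t_soil[0], liq[0], ice[0], e_left,
                                           cb, s_thick[0], dTf);
          t_soil[0] = as<double>(ap["temp"]);
          liq[0] = as<double>(ap["liquid"]);
          ice[0] = as<double>(ap["ice"]);
        }
      } else {
        swe -= melt; cum_melt += melt; pool_infil += melt; t_snow = 0.0;
      }
    }

    // daily aggregation
    acc_t10 += probe_temp();
    acc_depth += swe / snow_rho;
    acc_alb += alb;
    tskin_min = std::min(tskin_min, tskin);
    ++step_in_day;
    if (step_in_day == steps_per_day) {
      // end-of-day soil water bucket
      double e_pre_bucket = stack_energy();
      NumericVector icev(ice.begin(), ice.end());
      List bu = cpp_bucket_update(liq, icev, s_thick, s_por, s_fc, s_wp,
                                  pool_infil, pool_evap);
      NumericVector liq2 = bu["liquid"];
      for (int i = 0; i < ns; ++i) liq[i] = liq2[i];
      cum_infil += pool_infil;
      cum_evap += as<double>(bu["evap_actual"]);
      cum_drain += as<double>(bu["drainage"]);
      cum_runoff += as<double>(bu["runoff"]);
      water_closure_max = std::max(water_closure_max,
                                   std::fabs(as<double>(bu["closure_error_mm"])));
      cum_adv += stack_energy() - e_pre_bucket;  // enthalpy advected by water
      pool_infil = 0.0; pool_evap = 0.0;

      out_t10[day] = acc_t10 / steps_per_day;
      out_snowdepth[day] = acc_depth / steps_per_day;
      out_swe[day] = swe;
      out_albedo[day] = acc_alb / steps_per_day;
      out_tskin_min[day] = tskin_min;
      acc_t10 = acc_depth = acc_alb = 0.0; tskin_min = 1e9;
      step_in_day = 0; ++day;
    }
  }

  double e_end = stack_energy() + res_energy();
  double ledger_residual = (e_end - e_start) - (cum_G + cum_adv + cum_ext);

  return List::create(
    _["t10_daily_mean"] = out_t10,
    _["snow_depth_m"] = out_snowdepth,
    _["swe_mm"] = out_swe,
    _["albedo"] = out_albedo,
    _["tskin_daily_min"] = out_tskin_min,
    _["final_temp"] = t_soil, _["final_liquid"] = liq, _["final_ice"] = ice,
    _["energy"] = List::create(
      _["cum_ground_flux_j"] = cum_G, _["cum_abs_ground_flux_j"] = cum_absG,
      _["advected_j"] = cum_adv, _["external_j"] = cum_ext,
      _["stored_change_j"] = e_end - e_start,
      _["ledger_residual_j"] = ledger_residual,
      _["solver_closure_j"] = solver_closure),
    _["water"] = List::create(
      _["infiltration_mm"] = cum_infil, _["evaporation_mm"] = cum_evap,
      _["drainage_mm"] = cum_drain, _["runoff_mm"] = cum_runoff,
      _["step_closure_max_mm"] = water_closure_max),
    _["snow"] = List::create(
      _["snowfall_mm"] = cum_snowfall, _["melt_mm"] = cum_melt,
      _["final_swe_mm"] = swe));
}
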