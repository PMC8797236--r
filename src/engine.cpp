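// Coupled CBRD / ionic-dynamics engine on the (t, t*, x) grid.
//
// Units: mV, ms, mM, mS/cm2, uA/cm2, um. The time-since-spike (t*) grid is
// uniform with bin width equal to dt (characteristics-aligned transport);
// the last bin absorbs all older neurons and is treated as a
// quasi-stationary pool. Gating and hazard evaluations go through lookup
// tables built once per run; an active-window optimisation skips t* bins
// that carry no probability mass (state advects with mass, so empty bins
// cannot influence any observable).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------- RNG ----
// splitmix64 for seeding, xoshiro-style xorshift for the streams; one
// independent stream per spatial node so that changing nx does not
// silently reorder the noise.
static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s0, s1;
  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master ^ (0xd2b74407b1ce6e93ULL * (stream + 1));
    s0 = splitmix64(x);
    s1 = splitmix64(x);
    if (!s0 && !s1) s0 = 1;
  }
  inline uint64_t next() { // xorshift128+
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() { // Box-Muller, deterministic across platforms
    if (have) { have = false; return cached; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 6.283185307179586 * u2;
    cached = r * std::sin(a);
    have = true;
    return r * std::cos(a);
  }
  bool have = false;
  double cached = 0.0;
};

// ------------------------------------------------------------- tables ----
struct Tab1 {
  double lo = 0, inv = 0;
  std::vector<double> v;
  void build(double lo_, double hi_, int n, double (*f)(double, const void *),
             const void *ctx) {
    lo = lo_;
    inv = (n - 1) / (hi_ - lo_);
    v.resize(n);
    for (int i = 0; i < n; ++i) v[i] = f(lo_ + i / inv, ctx);
  }
  inline double at(double x) const {
    double t = (x - lo) * inv;
    if (t <= 0) return v.front();
    if (t >= (double)(v.size() - 1)) return v.back();
    int i = (int)t;
    double w = t - i;
    return v[i] + w * (v[i + 1] - v[i]);
  }
};

static double poly_haz(double T) {
  return std::exp(0.0061 - 1.12 * T - 0.257 * T * T - 0.072 * T * T * T -
                  0.0117 * T * T * T * T);
}

// A * tau_m as a function of (T, ln k); bilinear
struct HazTab {
  double Tlo = -3.0, Thi = 6.0, klo = std::log(0.002), khi = std::log(60.0);
  int nT = 901, nk = 121;
  std::vector<double> v;
  void build() {
    v.resize((size_t)nT * nk);
    for (int i = 0; i < nT; ++i) {
      double T = Tlo + (Thi - Tlo) * i / (nT - 1);
      for (int j = 0; j < nk; ++j) {
        double k = std::exp(klo + (khi - klo) * j / (nk - 1));
        double a = poly_haz(T) *
                   (1.0 - std::pow(1.0 + k, -0.71 + 0.0825 * (T + 3.0)));
        v[(size_t)i * nk + j] = a > 0 ? a : 0;
      }
    }
  }
  inline double at(double T, double k) const {
    double ti = (T - Tlo) / (Thi - Tlo) * (nT - 1);
    if (ti < 0) ti = 0;
    if (ti > nT - 1.000001) ti = nT - 1.000001;
    double ki = (std::log(k) - klo) / (khi - klo) * (nk - 1);
    if (ki < 0) ki = 0;
    if (ki > nk - 1.000001) ki = nk - 1.000001;
    int i = (int)ti, j = (int)ki;
    double wi = ti - i, wj = ki - j;
    const double *p = &v[(size_t)i * nk + j];
    double a = p[0] + wj * (p[1] - p[0]);
    double b = p[nk] + wj * (p[nk + 1] - p[nk]);
    return a + wi * (b - a);
  }
};

// exp(-T^2)/(1+erf(T)) with stable tail
static double bshape(double T) {
  if (T <= -5.0) {
    double x = -T;
    return x * std::sqrt(M_PI) / (1.0 - 1.0 / (2 * x * x) + 3.0 / (4 * x * x * x * x));
  }
  return std::exp(-T * T) / (1.0 + std::erf(T));
}

// gating rate helpers (x/(exp(x/s)-1) with removable singularity)
static inline double expdiv(double x, double s) {
  if (std::fabs(x) < 1e-3) return s - x / 2 + x * x / (12 * s);
  return x / std::expm1(x / s);
}
static double aDR(double U) { return -0.032 * expdiv(U + 48, -5); }
static double bDR(double U) { return 0.5 * std::exp(-(U + 53) / 40); }
static double aM(double U) { return -0.0001 * expdiv(U + 30, -9); }
static double bM(double U) { return 0.0001 * expdiv(U + 30, 9); }
static double am_(double U) { return -0.32 * expdiv(U + 50, -4); }
static double bm_(double U) { return 0.28 * expdiv(U + 23, 5); }
static double ah_(double U) { return 0.128 * std::exp(-(U + 46) / 18); }
static double bh_(double U) { return 4.0 / (1.0 + std::exp(-(U + 23) / 5)); }

struct GateTabCtx { double dt; };
static double ninfDR(double U, const void *) { double a = aDR(U), b = bDR(U); return a / (a + b); }
static double edecDR(double U, const void *c) {
  double dt = ((const GateTabCtx *)c)->dt;
  return std::exp(-(aDR(U) + bDR(U)) * dt);
}
static double ninfM(double U, const void *) { double a = aM(U), b = bM(U); return a / (a + b); }
static double edecM(double U, const void *c) {
  double dt = ((const GateTabCtx *)c)->dt;
  return std::exp(-(aM(U) + bM(U)) * dt);
}
struct FnmdaCtx { double Mg; };
static double fnmda_(double U, const void *c) {
  return 1.0 / (1.0 + (((const FnmdaCtx *)c)->Mg / 3.57) * std::exp(-0.062 * U));
}
static double sigDB(double U, const void *) { // sigmoid((U+40)/7)
  return 1.0 / (1.0 + std::exp(-(U + 40.0) / 7.0));
}
static double expg_(double g, const void *c) { // exp(-g*dt)
  return std::exp(-g * ((const GateTabCtx *)c)->dt);
}
static double btab_(double T, const void *) { return bshape(T); }

// --------------------------------------------------------- parameters ----
struct Par {
  double C, g_DR, g_M_E, g_KCa_E, g_Na_rep, V_Na_rep, g_DR_rep;
  double g_KL, g_ClL, g_NaL;
  double V_L, gL_E, gL_I;   // voltage-equation leak
  double VL_E, VL_I;        // leak reversals holding rest at V_L
  double V_reset, dt_AP, V_th0_E, V_th0_I, n_DR_reset;
  double V_DB, DB_slope, DB_amp, tau_Uinf;
  double sigma_V0, tau_Noise;
  double I_noise, tau_OU; // current density amplitude uA/cm2
  double g_AMPA_E_max, g_AMPA_I, g_NMDA_E, g_NMDA_I, g_GABA_E, g_GABA_I;
  double V_AMPA, V_NMDA, Mg;
  double tr_A, td_A, tr_N, td_N, tr_G, td_G, ts_A, ts_N, ts_G;
  double tau_glu, tau_GABA, u_glu, u_GABA;
  double gamma_ion, beta_vol, alpha_I, I_pump_max, I_KCC2_max, I_NKCC1_max_I;
  double q_Na, frac_K_glu, frac_Na_glu, D_bath, K_bath, nernst;
  double HCO3_i, HCO3_o;
  double tau_Ca, chi_Ca, V_Ca, alpha_KCa, beta_KCa;
  double k1_glia, B_max, K_half_glia, K_slope_glia;
  double tau_v, beta0_v, v_gain, pi_scale;
  bool sigma_sqrt, pump_kinetic, gaba_literal, glia_on, vol_dyn;
  bool kcc2_literal, anchor_baseline;
  double J0K_E, J0Na_E, J0K_I, J0Na_I, J0Cl_E, J0Cl_I;
  double wK_E, wK_I, VK0_ref; // K-leak share of the voltage-equation leak
  double dt, D1d, dx, lambda, a2a_frac;
  int nx, nb, jfroz, nsteps, tr_stride, fd_stride, s1, s2;
  double nM_reset;
};

static double getd(const List &L, const char *n) { return as<double>(L[n]); }

// ----------------------------------------------------- pump (kinetic) ----
static double pump_kin(double Umv, double Ki, double Ko, double Nai_c,
                       double Nao_c, double Imax) {
  double U = Umv / 1000.0;
  double Nai = Nai_c / (2.49 * std::exp(-0.386 * U));
  double Nae = Nao_c / (15.5 * std::exp(12.1 * U));
  double Kti = Ki / 0.5, Kte = Ko / 0.213;
  double Hp = 1e-4, MgATP = 3.904;
  double Pi = 4.2 / (1 + Ki / 292 + Hp / 6.77 + Nai_c / 224);
  double den_i = std::pow(1 + Nai, 3) + (1 + Kti) * (1 + Kti) - 1;
  double den_e = std::pow(1 + Nae, 3) + (1 + Kte) * (1 + Kte) - 1;
  double a1p = 1050 * Nai * Nai * Nai / den_i;
  double a2p = 481;
  double a3p = 2000 * Kte * Kte / den_e;
  double a4p = 320 * MgATP / (1 + MgATP);
  double a1m = 8.605;
  double a2m = 40 * Nae * Nae * Nae / den_e;
  double a3m = 79300 * Pi * Hp / (1 + MgATP);
  double a4m = 40 * Kti * Kti / den_i;
  double fwd = a1p * a2p * a3p * a4p, bwd = a1m * a2m * a3m * a4m;
  double S = a1p * a2p * a3p + a1p * a2p * a4p + a3p * a2p * a4p +
             a2p * a3p * a4p + a1m * a3m * a4m + a1m * a2m * a4m +
             a2m * a3m * a4m + a1m * a2m * a3m + a4p * a2m * a1m +
             a4p * a2m * a1p + a4m * a2p * a3p + a4m * a2p * a3m +
             a1p * a2p * a3m + a1p * a2m * a3m + a1m * a4m * a3p +
             a1m * a3p * a4p;
  return Imax * (fwd - bwd) / (16.8 * S);
}

static double pump_sig(double Ko, double Nai, double Imax) {
  return Imax / ((1 + std::exp(3.5 - Ko)) * (1 + std::exp((25 - Nai) / 3)));
}

// ------------------------------------------------- population storage ----
struct Pop {
  // arrays laid out [node][bin]
  std::vector<double> rho, U, nDR, nM, nKCa, Uinf, Tprev;
  std::vector<int> act_lo;          // lowest active t* bin per node
  std::vector<double> nu;           // firing rate per node (1/ms)
  std::vector<double> Ubar;         // density-weighted mean voltage
  std::vector<double> IKact;        // mean voltage-gated K current
  std::vector<double> mass;         // density integral diagnostic
  std::vector<double> nKCa_tp, Uinf_tp; // reset values for next injection
  bool isE;
  int nx, nb;
  void init(int nx_, int nb_, double U0, bool isE_, double dt) {
    nx = nx_; nb = nb_; isE = isE_;
    size_t n = (size_t)nx * nb;
    rho.assign(n, 0.0);
    U.assign(n, U0);
    double a = aDR(U0), b = bDR(U0);
    nDR.assign(n, a / (a + b));
    a = aM(U0); b = bM(U0);
    nM.assign(n, isE ? a / (a + b) : 0.0);
    nKCa.assign(n, 0.0);
    Uinf.assign(n, U0);
    Tprev.assign(n, 5.0);
    act_lo.assign(nx, nb - 1);
    nu.assign(nx, 0.0);
    Ubar.assign(nx, U0);
    IKact.assign(nx, 0.0);
    mass.assign(nx, 1.0);
    nKCa_tp.assign(nx, 0.0);
    Uinf_tp.assign(nx, U0);
    for (int i = 0; i < nx; ++i) rho[(size_t)i * nb + nb - 1] = 1.0 / dt;
  }
};

// representative neuron state
struct RepNeuron {
  double V, m, h, nDR, nM, nKCa;
  void init(double U0, bool isE) {
    V = U0;
    double a = am_(U0), b = bm_(U0);
    m = a / (a + b);
    a = ah_(U0); b = bh_(U0);
    h = a / (a + b);
    a = aDR(U0); b = bDR(U0);
    nDR = a / (a + b);
    a = aM(U0); b = bM(U0);
    nM = isE ? a / (a + b) : 0.0;
    nKCa = 0.0;
  }
};

// one substepped update of a representative neuron
static void rep_step(RepNeuron &st, bool isE, const Par &P, double gA,
                     double gN0, double gG, double VK, double VGABA,
                     double gL, double VLp, double Iext, double Ca, double dt,
                     const Tab1 &fN) {
  int nsub = (int)std::ceil(dt / 0.05);
  double h = dt / nsub;
  double gM = isE ? P.g_M_E : 0.0, gKCa = isE ? P.g_KCa_E : 0.0;
  double rKCa = P.alpha_KCa * Ca * Ca + P.beta_KCa;
  double nKinf = P.alpha_KCa * Ca * Ca / rKCa;
  for (int s = 0; s < nsub; ++s) {
    double V = st.V;
    double a, b, r;
    a = am_(V); b = bm_(V); r = a + b;
    st.m = a / r + (st.m - a / r) * std::exp(-r * h);
    a = ah_(V); b = bh_(V); r = a + b;
    st.h = a / r + (st.h - a / r) * std::exp(-r * h);
    a = aDR(V); b = bDR(V); r = a + b;
    st.nDR = a / r + (st.nDR - a / r) * std::exp(-r * h);
    if (isE) {
      a = aM(V); b = bM(V); r = a + b;
      st.nM = a / r + (st.nM - a / r) * std::exp(-r * h);
      st.nKCa = nKinf + (st.nKCa - nKinf) * std::exp(-rKCa * h);
    }
    double gvg = P.g_DR_rep * std::pow(st.nDR, 4) + gM * st.nM +
                 gKCa * st.nKCa * st.nKCa;
    double gNa = P.g_Na_rep * st.m * st.m * st.m * st.h;
    double gNs = gN0 * fN.at(V);
    double gtot = gL + gvg + gNa + gA + gNs + gG;
    double num = gL * VLp + gvg * VK + gNa * P.V_Na_rep + gA * P.V_AMPA +
                 gNs * P.V_NMDA + gG * VGABA + Iext;
    double Ueq = num / gtot;
    st.V = Ueq + (st.V - Ueq) * std::exp(-gtot * h / P.C);
  }
}

// fast-gate reset values: drive the representative E neuron with a 2-ms
// suprathreshold pulse and sample gating at the voltage maximum.
static double compute_nM_reset(const Par &P, double VK, double gL) {
  RepNeuron st;
  st.init(P.V_L, true);
  Tab1 fN;
  FnmdaCtx fc{P.Mg};
  fN.build(-120, 60, 361, fnmda_, &fc);
  double dt = 0.01, Vmax = -1e9, nM_at = st.nM;
  for (int i = 0; i < 5000; ++i) {
    double t = i * dt;
    double Iext = (t >= 10 && t < 12) ? 30.0 : 0.0;
    rep_step(st, true, P, 0, 0, 0, VK, -70, gL, P.V_L, Iext, 0, dt, fN);
    if (st.V > Vmax) { Vmax = st.V; nM_at = st.nM; }
  }
  return nM_at;
}

// ------------------------------------------------------- main engine ----
// [[Rcpp::export]]
List cpp_run_scenario(List cfg) {
  Par P;
  List pl = cfg["params"];
  P.C = getd(pl, "C");
  P.g_DR = getd(pl, "g_DR");
  P.g_M_E = getd(pl, "g_M_E");
  P.g_KCa_E = getd(pl, "g_KCa_E");
  P.g_Na_rep = getd(pl, "g_Na_rep");
  P.g_DR_rep = getd(pl, "g_DR_rep");
  P.V_Na_rep = getd(pl, "V_Na_rep");
  P.g_KL = getd(pl, "g_KL");
  P.g_ClL = getd(pl, "g_ClL");
  P.g_NaL = getd(pl, "g_NaL");
  P.V_reset = getd(pl, "V_reset");
  P.dt_AP = getd(pl, "dt_AP");
  P.V_th0_E = getd(pl, "V_th0_E");
  P.V_th0_I = getd(pl, "V_th0_I");
  P.n_DR_reset = getd(pl, "n_DR_reset");
  P.V_DB = getd(pl, "V_DB");
  P.DB_slope = getd(pl, "DB_slope");
  P.DB_amp = getd(pl, "DB_amp");
  P.tau_Uinf = getd(pl, "tau_Uinf");
  P.sigma_V0 = getd(pl, "sigma_V0");
  P.tau_Noise = getd(pl, "tau_Noise");
  P.I_noise = getd(pl, "I_noise_pA") * getd(pl, "noise_gain") * 1e-6 /
              getd(pl, "area_cm2");
  P.tau_OU = getd(pl, "tau_OU");
  P.g_AMPA_E_max = getd(pl, "g_AMPA_E");
  P.g_AMPA_I = getd(pl, "g_AMPA_I");
  P.g_NMDA_E = getd(pl, "g_NMDA_E");
  P.g_NMDA_I = getd(pl, "g_NMDA_I");
  P.g_GABA_E = getd(pl, "g_GABA_E");
  P.g_GABA_I = getd(pl, "g_GABA_I");
  P.V_AMPA = getd(pl, "V_AMPA");
  P.V_NMDA = getd(pl, "V_NMDA");
  P.Mg = getd(pl, "Mg");
  P.tr_A = getd(pl, "tau_r_AMPA"); P.td_A = getd(pl, "tau_d_AMPA");
  P.tr_N = getd(pl, "tau_r_NMDA"); P.td_N = getd(pl, "tau_d_NMDA");
  P.tr_G = getd(pl, "tau_r_GABA"); P.td_G = getd(pl, "tau_d_GABA");
  P.tau_glu = getd(pl, "tau_glu");
  P.tau_GABA = getd(pl, "tau_GABA");
  P.u_glu = getd(pl, "u_glu");
  P.u_GABA = getd(pl, "u_GABA");
  P.gamma_ion = getd(pl, "gamma_ion");
  P.beta_vol = getd(pl, "beta_vol");
  P.alpha_I = getd(pl, "alpha_I");
  P.I_pump_max = getd(pl, "I_pump_max");
  P.I_KCC2_max = getd(pl, "I_KCC2_max");
  P.I_NKCC1_max_I = getd(pl, "I_NKCC1_max_I");
  P.q_Na = getd(pl, "q_Na");
  P.frac_K_glu = getd(pl, "frac_K_glu");
  P.frac_Na_glu = getd(pl, "frac_Na_glu");
  P.D_bath = getd(pl, "D_bath");
  P.K_bath = getd(pl, "K_bath");
  P.nernst = getd(pl, "nernst_mV");
  P.HCO3_i = getd(pl, "HCO3_i");
  P.HCO3_o = getd(pl, "HCO3_o");
  P.tau_Ca = getd(pl, "tau_Ca");
  P.chi_Ca = getd(pl, "chi_Ca");
  P.V_Ca = getd(pl, "V_Ca");
  P.alpha_KCa = getd(pl, "alpha_KCa");
  P.beta_KCa = getd(pl, "beta_KCa");
  P.k1_glia = getd(pl, "k1_glia");
  P.B_max = getd(pl, "B_max");
  P.K_half_glia = getd(pl, "K_half_glia");
  P.K_slope_glia = getd(pl, "K_slope_glia");
  P.tau_v = getd(pl, "tau_v");
  P.beta0_v = getd(pl, "beta0_v");
  P.v_gain = getd(pl, "v_gain");
  P.pi_scale = getd(pl, "pi_scale");

  P.dt = getd(cfg, "dt_ms");
  P.nx = as<int>(cfg["nx"]);
  P.D1d = getd(cfg, "D1d_um2_ms");
  P.dx = getd(cfg, "dx_um");
  P.a2a_frac = getd(cfg, "all_to_all_fraction");
  P.sigma_sqrt = as<std::string>(cfg["sigma_V_form"]) == "sqrt";
  P.pump_kinetic = as<std::string>(cfg["pump_model"]) == "kinetic";
  P.kcc2_literal = as<std::string>(cfg["kcc2_form"]) == "literal";
  P.anchor_baseline = as<bool>(cfg["anchor_baseline"]);
  P.gaba_literal = as<bool>(cfg["gaba_reversal_literal"]);
  P.glia_on = as<bool>(cfg["glia_on"]);
  P.vol_dyn = as<bool>(cfg["volume_dynamic"]);
  P.nb = as<int>(cfg["nb"]);
  P.jfroz = (int)std::ceil(P.dt_AP / P.dt) - 1; // bins 0..jfroz frozen
  P.nsteps = as<int>(cfg["nsteps"]);
  P.tr_stride = as<int>(cfg["trace_stride"]);
  P.fd_stride = as<int>(cfg["field_stride"]);
  P.s1 = as<int>(cfg["s1"]) - 1;
  P.s2 = as<int>(cfg["s2"]) - 1;
  uint64_t seed = (uint64_t)as<double>(cfg["seed"]);
  NumericMatrix Kmat = cfg["kernel"]; // nx x nx row-normalized (identity ok)
  NumericVector gA_E_x = cfg["g_AMPA_E_profile"]; // per node
  bool use_kernel = as<bool>(cfg["use_kernel"]);

  // normalizing synaptic timescales
  auto tscale = [](double tr, double td) {
    if (std::fabs(tr - td) < 1e-9 * tr) return tr * std::exp(1.0);
    double q = td / tr;
    return (tr - td) / (std::pow(q, td / (tr - td)) - std::pow(q, tr / (tr - td)));
  };
  P.ts_A = tscale(P.tr_A, P.td_A);
  P.ts_N = tscale(P.tr_N, P.td_N);
  P.ts_G = tscale(P.tr_G, P.td_G);

  const int nx = P.nx, nb = P.nb;
  const double dt = P.dt;

  // initial ionic state
  double K_i0 = getd(pl, "K_i0"), K_o0 = getd(pl, "K_o0");
  double Cl_o0 = getd(pl, "Cl_o0"), Na_o0 = getd(pl, "Na_o0");
  double Na_i0 = getd(pl, "Na_i0");
  double Cl_iE0 = getd(pl, "Cl_iE0"), Cl_iI0 = getd(pl, "Cl_iI0");

  std::vector<double> K_iE(nx, K_i0), K_iI(nx, K_i0);
  std::vector<double> Cl_iE(nx, Cl_iE0), Cl_iI(nx, Cl_iI0);
  std::vector<double> Na_iE(nx, Na_i0), Na_iI(nx, Na_i0);
  std::vector<double> K_o(nx, K_o0), Cl_o(nx, Cl_o0), Na_o(nx, Na_o0);
  std::vector<double> Ca(nx, 0.0), Bgl(nx, 0.0), vol(nx, 1.0);
  std::vector<double> Wk(nx), Wcl(nx), Wna(nx); // volume-weighted products
  for (int i = 0; i < nx; ++i) {
    Wk[i] = K_o[i]; Wcl[i] = Cl_o[i]; Wna[i] = Na_o[i];
  }
  if (P.glia_on) {
    for (int i = 0; i < nx; ++i) {
      double k2 = P.k1_glia /
                  (1 + std::exp(-(K_o[i] - P.K_half_glia) / P.K_slope_glia));
      Bgl[i] = P.k1_glia * P.B_max / (P.k1_glia + k2);
    }
  }

  // resting potentials from leak reversals
  auto nernst3 = [&](double Ki, double Ko, double Cli, double Clo, double Nai,
                     double Nao, double &VK, double &VCl, double &VNa) {
    VK = P.nernst * std::log(Ko / Ki);
    VCl = P.nernst * std::log(Cli / Clo);
    VNa = P.nernst * std::log(Nao / Nai);
  };
  double VK0, VClE0, VNa0, VClI0, d1, d2;
  nernst3(K_i0, K_o0, Cl_iE0, Cl_o0, Na_i0, Na_o0, VK0, VClE0, VNa0);
  nernst3(K_i0, K_o0, Cl_iI0, Cl_o0, Na_i0, Na_o0, d1, VClI0, d2);
  // voltage-equation leak: fixed reversal V_L; the leak conductance of
  // each population is set so that the total rest conductance (leak +
  // voltage-gated at rest) matches C / tau_m0 as printed
  P.V_L = getd(pl, "V_L");
  double tau_m0_E = getd(pl, "tau_m0_E");
  double tau_m0_I = getd(pl, "tau_m0_I");
  double aa = aDR(P.V_L), bb = bDR(P.V_L);
  double nDR0r = aa / (aa + bb);
  aa = aM(P.V_L); bb = bM(P.V_L);
  double nM0r = aa / (aa + bb);
  double gvg0E = P.g_DR * std::pow(nDR0r, 4) + P.g_M_E * nM0r;
  double gvg0I = P.g_DR * std::pow(nDR0r, 4);
  double gpassE = P.C / tau_m0_E;
  double gpassI = P.C / tau_m0_I;
  P.gL_E = std::max(1e-4, gpassE - gvg0E);
  P.gL_I = std::max(1e-4, gpassI - gvg0I);
  // electrogenic pump: one net charge leaves per cycle, so the membrane
  // sees a hyperpolarizing current equal to I_pump (the paper's stated
  // discharge terminator); its resting value at the initial state:
  double Ip0 = P.pump_kinetic
                   ? pump_kin(P.V_L, K_i0, K_o0, Na_i0, Na_o0, P.I_pump_max)
                   : pump_sig(K_o0, Na_i0, P.I_pump_max);
  if (Ip0 < 0) Ip0 = 0;
  // leak reversal back-computed so the rest point (leak + resting
  // voltage-gated K at the initial V_K + resting pump current) sits
  // exactly at V_L
  P.VL_E = P.V_L + (gvg0E * (P.V_L - VK0) + Ip0) / P.gL_E;
  P.VL_I = P.V_L + (gvg0I * (P.V_L - VK0) + Ip0) / P.gL_I;
  double U0E = P.V_L, U0I = P.V_L;

  P.nM_reset = compute_nM_reset(P, VK0, P.gL_E);

  // baseline anchoring: constant correction fluxes that make the nominal
  // initial state an exact K/Na flux equilibrium (the resting micro-
  // imbalances of the printed parameter set otherwise accumulate over
  // minutes and shift the interictal baseline). Chloride is deliberately
  // left uncorrected: its slow loading is the ignition clock.
  P.J0K_E = P.J0Na_E = P.J0K_I = P.J0Na_I = 0.0;
  P.J0Cl_E = P.J0Cl_I = 0.0;
  if (P.anchor_baseline) {
    auto rest_j0 = [&](double U0, double VK, double VCl, double VNa,
                       bool isE, double &J0K, double &J0Na) {
      double a = aDR(U0), b = bDR(U0);
      double nDR0 = a / (a + b);
      double gM0 = 0.0;
      if (isE) {
        a = aM(U0); b = bM(U0);
        gM0 = P.g_M_E * a / (a + b);
      }
      double gvg0 = P.g_DR * std::pow(nDR0, 4) + gM0;
      double IKleak0 = P.g_KL * (U0 - VK);
      double IKact0 = gvg0 * (U0 - VK);
      double INaleak0 = P.g_NaL * (U0 - VNa);
      double Ip0 = P.pump_kinetic
                       ? pump_kin(U0, K_i0, K_o0, Na_i0, Na_o0, P.I_pump_max)
                       : pump_sig(K_o0, Na_i0, P.I_pump_max);
      if (Ip0 < 0) Ip0 = 0;
      double u0 = VK - VCl;
      double IKCC2_0;
      if (P.kcc2_literal) {
        double dk = u0 - 40.0;
        if (std::fabs(dk) < 1e-6) dk = -1e-6;
        IKCC2_0 = P.I_KCC2_max * u0 / dk;
      } else {
        IKCC2_0 = P.I_KCC2_max * u0 / (std::fabs(u0) + 40.0);
      }
      double INKCC1_0 =
          isE ? 0.0 : P.I_NKCC1_max_I * (VNa + VK - 2 * VCl) / P.nernst;
      J0K = IKleak0 + IKact0 - 2 * Ip0 - IKCC2_0 - INKCC1_0;
      J0Na = INaleak0 + 3 * Ip0 - INKCC1_0;
      // chloride is deliberately left unanchored: the printed initial
      // chloride is far from its passive equilibrium, and the slow
      // interictal chloride loading is part of the ignition mechanism
    };
    rest_j0(U0E, VK0, VClE0, VNa0, true, P.J0K_E, P.J0Na_E);
    double VKI0 = VK0, VNaI0 = VNa0;
    rest_j0(U0I, VKI0, VClI0, VNaI0, false, P.J0K_I, P.J0Na_I);
  }
  // the potassium share of the voltage-equation leak carries a Nernst
  // reversal: the leak reversal tracks V_K with weight gKL/gL, providing
  // the [K+]o -> excitability coupling that maintains discharges
  double kw = getd(pl, "k_leak_coupling");
  P.wK_E = kw * P.g_KL / P.gL_E;
  P.wK_I = kw * P.g_KL / P.gL_I;
  P.VK0_ref = VK0;

  // tables
  GateTabCtx gtc{dt};
  FnmdaCtx fc{P.Mg};
  Tab1 tb_ninfDR, tb_edecDR, tb_ninfM, tb_edecM, tb_fN, tb_sig, tb_expg, tb_B;
  tb_ninfDR.build(-150, 80, 4601, ninfDR, nullptr);
  tb_edecDR.build(-150, 80, 4601, edecDR, &gtc);
  tb_ninfM.build(-150, 80, 4601, ninfM, nullptr);
  tb_edecM.build(-150, 80, 4601, edecM, &gtc);
  tb_fN.build(-150, 80, 4601, fnmda_, &fc);
  tb_sig.build(-150, 80, 4601, sigDB, nullptr);
  tb_expg.build(0, 25, 12501, expg_, &gtc);
  tb_B.build(-8, 8, 3201, btab_, nullptr);
  HazTab tb_A;
  tb_A.build();

  Pop E, I;
  E.init(nx, nb, U0E, true, dt);
  I.init(nx, nb, U0I, false, dt);

  // synapse kernel states per node: m and dm for (A,N,G) x (E,I)
  std::vector<double> mAE(nx, 0), dAE(nx, 0), mNE(nx, 0), dNE(nx, 0),
      mGE(nx, 0), dGE(nx, 0), mAI(nx, 0), dAI(nx, 0), mNI(nx, 0), dNI(nx, 0),
      mGI(nx, 0), dGI(nx, 0);
  std::vector<double> xglu(nx, 1.0), xgaba(nx, 1.0);
  std::vector<double> Iou(nx, 0.0);
  std::vector<double> IpE(nx, Ip0), IpI(nx, Ip0);
  std::vector<Rng> rng(nx);
  for (int i = 0; i < nx; ++i) rng[i].seed(seed, (uint64_t)i);
  double ou_a = std::exp(-dt / P.tau_OU);
  // the printed amplitude is read as the quasi-static voltage-equivalent
  // drive (25 pA x R_in); the OU low-pass attenuation by the membrane is
  // compensated so the stationary voltage fluctuation SD equals that value
  double ou_gain = std::sqrt((P.tau_OU + tau_m0_I) / P.tau_OU);
  double ou_b = P.I_noise * ou_gain * std::sqrt(1 - ou_a * ou_a);

  RepNeuron repE1, repI1, repE2, repI2;
  repE1.init(U0E, true);
  repE2.init(U0E, true);
  repI1.init(U0I, false);
  repI2.init(U0I, false);

  // baseline osmolarity sums
  double sum_i0 = (1 - P.alpha_I) * (K_i0 + Cl_iE0 + Na_i0) +
                  P.alpha_I * (K_i0 + Cl_iI0 + Na_i0);
  double sum_o0 = K_o0 + Cl_o0 + Na_o0;

  // output buffers
  int ntr = P.nsteps / P.tr_stride + 1;
  int nfd = P.nsteps / P.fd_stride + 1;
  const int NTRC = 28;
  NumericMatrix traces(ntr, NTRC);
  NumericMatrix fUE(nfd, nx), fKo(nfd, nx), fClE(nfd, nx), fNaE(nfd, nx),
      fvol(nfd, nx), fnuE(nfd, nx), fnuI(nfd, nx);
  NumericVector tr_time(ntr), fd_time(nfd);
  int itr = 0, ifd = 0;
  double mass_dev_max = 0.0;
  int floor_warnings = 0;

  std::vector<double> phiE(nx), phiI(nx), lapK(nx);
  std::vector<double> VK_E(nx), VCl_E(nx), VNa_E(nx), VG_E(nx);
  std::vector<double> VK_I(nx), VCl_I(nx), VNa_I(nx), VG_I(nx);

  const double sq2 = std::sqrt(2.0), twoosqpi = 2.0 / std::sqrt(M_PI);
  const double eU = std::exp(-dt / P.tau_Uinf);
  bool blown = false;
  int blow_step = -1;

  for (int step = 0; step < P.nsteps && !blown; ++step) {
    // --- noise ---
    for (int i = 0; i < nx; ++i)
      Iou[i] = Iou[i] * ou_a + ou_b * rng[i].gauss();

    // --- spatial kernels ---
    double meanE = 0, meanI = 0;
    for (int i = 0; i < nx; ++i) { meanE += E.nu[i]; meanI += I.nu[i]; }
    meanE /= nx; meanI /= nx;
    if (use_kernel) {
      for (int i = 0; i < nx; ++i) {
        double se = 0, si = 0;
        for (int j = 0; j < nx; ++j) {
          se += Kmat(i, j) * E.nu[j];
          si += Kmat(i, j) * I.nu[j];
        }
        phiE[i] = se; phiI[i] = si;
      }
    } else {
      for (int i = 0; i < nx; ++i) { phiE[i] = E.nu[i]; phiI[i] = I.nu[i]; }
    }
    if (P.a2a_frac > 0) {
      for (int i = 0; i < nx; ++i) {
        phiE[i] = (1 - P.a2a_frac) * phiE[i] + P.a2a_frac * meanE;
        phiI[i] = (1 - P.a2a_frac) * phiI[i] + P.a2a_frac * meanI;
      }
    }

    // --- synapses (second-order kernels; RK2 with substeps) ---
    auto syn = [&](double &m, double &dm, double phi, double tr, double td,
                   double ts) {
      int nsub = (dt > 0.5 * tr) ? (int)std::ceil(dt / (0.5 * tr)) : 1;
      double h = dt / nsub, a = tr * td, b = tr + td;
      for (int s = 0; s < nsub; ++s) {
        double f1m = dm, f1d = (ts * (1 - m) * phi - b * dm - m) / a;
        double mh = m + 0.5 * h * f1m, dh = dm + 0.5 * h * f1d;
        double f2d = (ts * (1 - mh) * phi - b * dh - mh) / a;
        m += h * dh;
        dm += h * f2d;
      }
      if (m < 0) { m = 0; if (dm < 0) dm = 0; }
    };
    for (int i = 0; i < nx; ++i) {
      syn(mAE[i], dAE[i], phiE[i], P.tr_A, P.td_A, P.ts_A);
      syn(mNE[i], dNE[i], phiE[i], P.tr_N, P.td_N, P.ts_N);
      syn(mGE[i], dGE[i], phiI[i], P.tr_G, P.td_G, P.ts_G);
      syn(mAI[i], dAI[i], phiE[i], P.tr_A, P.td_A, P.ts_A);
      syn(mNI[i], dNI[i], phiE[i], P.tr_N, P.td_N, P.ts_N);
      syn(mGI[i], dGI[i], phiI[i], P.tr_G, P.td_G, P.ts_G);
      // depression (exact for frozen phi)
      double r = 1 / P.tau_glu + P.u_glu * phiE[i];
      double xi = (1 / P.tau_glu) / r;
      xglu[i] = xi + (xglu[i] - xi) * std::exp(-r * dt);
      r = 1 / P.tau_GABA + P.u_GABA * phiI[i];
      xi = (1 / P.tau_GABA) / r;
      xgaba[i] = xi + (xgaba[i] - xi) * std::exp(-r * dt);
    }

    // --- reversal potentials per node/pop ---
    for (int i = 0; i < nx; ++i) {
      VK_E[i] = P.nernst * std::log(K_o[i] / K_iE[i]);
      VCl_E[i] = P.nernst * std::log(Cl_iE[i] / Cl_o[i]);
      VNa_E[i] = P.nernst * std::log(Na_o[i] / Na_iE[i]);
      VG_E[i] = P.nernst * std::log((4 * Cl_iE[i] + P.HCO3_i) /
                                    (4 * Cl_o[i] + P.HCO3_o));
      VK_I[i] = P.nernst * std::log(K_o[i] / K_iI[i]);
      VCl_I[i] = P.nernst * std::log(Cl_iI[i] / Cl_o[i]);
      VNa_I[i] = P.nernst * std::log(Na_o[i] / Na_iI[i]);
      VG_I[i] = P.nernst * std::log((4 * Cl_iI[i] + P.HCO3_i) /
                                    (4 * Cl_o[i] + P.HCO3_o));
    }

    // --- population transport + bin updates ---
    auto pop_step = [&](Pop &pp, int i, double gA, double gN0, double gG,
                        double VK, double VGABA, double Inoi, double Vth0,
                        double gpass, double gLp, double VLp, double Cai,
                        double Ipump_brake) {
      size_t o = (size_t)i * nb;
      double *rho = &pp.rho[o], *U = &pp.U[o], *nDR = &pp.nDR[o],
             *nM = &pp.nM[o], *nKCa = &pp.nKCa[o], *Uinf = &pp.Uinf[o],
             *Tprev = &pp.Tprev[o];
      int lo = pp.act_lo[i];
      // absorber merge + shift of the active window
      if (lo <= nb - 2) {
        double ra = rho[nb - 1], rb = rho[nb - 2], s = ra + rb;
        if (s > 0) {
          double wa = ra / s, wb = rb / s;
          U[nb - 1] = wa * U[nb - 1] + wb * U[nb - 2];
          nDR[nb - 1] = wa * nDR[nb - 1] + wb * nDR[nb - 2];
          nM[nb - 1] = wa * nM[nb - 1] + wb * nM[nb - 2];
          nKCa[nb - 1] = wa * nKCa[nb - 1] + wb * nKCa[nb - 2];
          Uinf[nb - 1] = wa * Uinf[nb - 1] + wb * Uinf[nb - 2];
          Tprev[nb - 1] = wa * Tprev[nb - 1] + wb * Tprev[nb - 2];
        }
        rho[nb - 1] = s;
        for (int j = nb - 2; j > lo; --j) {
          rho[j] = rho[j - 1]; U[j] = U[j - 1]; nDR[j] = nDR[j - 1];
          nM[j] = nM[j - 1]; nKCa[j] = nKCa[j - 1]; Uinf[j] = Uinf[j - 1];
          Tprev[j] = Tprev[j - 1];
        }
        rho[lo] = 0.0;
        if (lo < nb - 1) { lo += 1; pp.act_lo[i] = lo; }
      }
      // injection of last step's firing rate
      double inj = pp.nu[i];
      if (inj > 1e-7) {
        rho[0] = inj;
        nKCa[0] = pp.nKCa_tp[i];
        Uinf[0] = pp.Uinf_tp[i];
        lo = 0;
        pp.act_lo[i] = 0;
      } else if (inj > 0) {
        rho[nb - 1] += inj; // negligible mass goes straight to the pool
      }
      // per-bin update over the active window
      double isE = pp.isE ? 1.0 : 0.0;
      double gM = pp.isE ? P.g_M_E : 0.0;
      double gKCa = pp.isE ? P.g_KCa_E : 0.0;
      double rK = P.alpha_KCa * Cai * Cai + P.beta_KCa;
      double nKinf = P.alpha_KCa * Cai * Cai / rK;
      double eK = std::exp(-rK * dt);
      double removed = 0, massacc = 0, ubacc = 0, ikacc = 0;
      double relmax = -1; int jrel = nb - 1;
      double VG_used = P.gaba_literal ? VK : VGABA;
      for (int j = lo; j < nb; ++j) {
        if (j <= P.jfroz) {
          if (rho[j] < 1e-8) { massacc += rho[j]; continue; }
          U[j] = P.V_reset;
          nDR[j] = P.n_DR_reset;
          if (pp.isE) nM[j] = P.nM_reset;
          Uinf[j] = Uinf[j] + (P.V_reset - Uinf[j]) * (1 - eU);
          double gvg = P.g_DR * 0.0625 + gM * nM[j] + gKCa * nKCa[j] * nKCa[j];
          double fn = tb_fN.at(U[j]);
          double gsyn = gA + gN0 * fn + gG;
          double gtot = gLp + gvg + gsyn;
          double Vth = Vth0 + P.DB_amp * tb_sig.at(Uinf[j]);
          double sV = P.sigma_sqrt ? P.sigma_V0 * std::sqrt(1 + gsyn / gpass)
                                   : P.sigma_V0 * (1 + gsyn / gpass);
          Tprev[j] = (Vth - U[j]) / (sq2 * sV);
          massacc += rho[j];
          ubacc += U[j] * rho[j];
          ikacc += gvg * (U[j] - VK) * rho[j];
          continue;
        }
        if (rho[j] < 1e-8 && j != nb - 1) {
          // negligible mass: state advects with the mass it carries, so
          // bins holding none cannot influence any observable
          massacc += rho[j];
          continue;
        }
        double Uj = U[j];
        // gating (table-driven exponential Euler)
        double ni = tb_ninfDR.at(Uj), ed = tb_edecDR.at(Uj);
        nDR[j] = ni + (nDR[j] - ni) * ed;
        if (pp.isE) {
          ni = tb_ninfM.at(Uj); ed = tb_edecM.at(Uj);
          nM[j] = ni + (nM[j] - ni) * ed;
          nKCa[j] = nKinf + (nKCa[j] - nKinf) * eK;
        }
        double n2 = nDR[j] * nDR[j];
        double gvg = P.g_DR * n2 * n2 + gM * nM[j] + gKCa * nKCa[j] * nKCa[j];
        double fn = tb_fN.at(Uj);
        double gNs = gN0 * fn;
        double gsyn = gA + gNs + gG;
        double gtot = gLp + gvg + gsyn;
        double VLdyn = VLp + (pp.isE ? P.wK_E : P.wK_I) * (VK - P.VK0_ref);
        double num = gLp * VLdyn + gvg * VK + gA * P.V_AMPA +
                     gNs * P.V_NMDA + gG * VG_used + Inoi - Ipump_brake;
        double Ueq = num / gtot;
        double Un = Ueq + (Uj - Ueq) * tb_expg.at(gtot);
        U[j] = Un;
        Uinf[j] = Uinf[j] + (Un - Uinf[j]) * (1 - eU);
        double Vth = Vth0 + P.DB_amp * tb_sig.at(Uinf[j]);
        double sV = P.sigma_sqrt ? P.sigma_V0 * std::sqrt(1 + gsyn / gpass)
                                 : P.sigma_V0 * (1 + gsyn / gpass);
        double T = (Vth - Un) / (sq2 * sV);
        double dTdt = (T - Tprev[j]) / dt;
        Tprev[j] = T;
        double k = P.C / (gtot * P.tau_Noise);
        double A = tb_A.at(T, k) * gtot / P.C;
        double Bt = 0;
        if (dTdt < 0) {
          double bs = (T < -8) ? bshape(T) : tb_B.at(T);
          Bt = twoosqpi * (-dTdt) * bs;
        }
        double H = A + Bt;
        double f = H * dt;
        double dec = (f < 0.01) ? 1 - f * (1 - 0.5 * f * (1 - f / 3))
                                : std::exp(-f);
        double rem = rho[j] * (1 - dec);
        removed += rem;
        rho[j] *= dec;
        double rel = rho[j] * H;
        if (rel > relmax) { relmax = rel; jrel = j; }
        massacc += rho[j];
        ubacc += Un * rho[j];
        ikacc += gvg * (Un - VK) * rho[j];
      }
      pp.nu[i] = removed; // mass/dt * dt: removed mass per dt = rate
      pp.mass[i] = (massacc + removed) * dt;
      double mtot = massacc * dt + removed * dt;
      if (mtot > 0) pp.Ubar[i] = ubacc * dt / (massacc * dt + 1e-300) ;
      pp.IKact[i] = ikacc * dt;
      pp.nKCa_tp[i] = nKCa[jrel];
      pp.Uinf_tp[i] = Uinf[jrel];
      (void)isE; (void)mtot;
    };

    for (int i = 0; i < nx; ++i) {
      double gAE = gA_E_x[i] * mAE[i] * xglu[i];
      double gNE = P.g_NMDA_E * mNE[i] * xglu[i];
      double gGE = P.g_GABA_E * mGE[i] * xgaba[i];
      pop_step(E, i, gAE, gNE, gGE, VK_E[i], VG_E[i],
               0.0, P.V_th0_E, gpassE, P.gL_E, P.VL_E, Ca[i], IpE[i]);
      double gAI = P.g_AMPA_I * mAI[i] * xglu[i];
      double gNI = P.g_NMDA_I * mNI[i] * xglu[i];
      double gGI = P.g_GABA_I * mGI[i] * xgaba[i];
      pop_step(I, i, gAI, gNI, gGI, VK_I[i], VG_I[i],
               Iou[i], P.V_th0_I, gpassI, P.gL_I, P.VL_I, 0.0, IpI[i]);
      double dev = std::fabs(E.mass[i] - 1.0);
      if (dev > mass_dev_max) mass_dev_max = dev;
      dev = std::fabs(I.mass[i] - 1.0);
      if (dev > mass_dev_max) mass_dev_max = dev;
    }

    // --- representative neurons at the electrode sites ---
    auto reps = [&](int i, RepNeuron &rE, RepNeuron &rI) {
      double gAE = gA_E_x[i] * mAE[i] * xglu[i];
      double gNE = P.g_NMDA_E * mNE[i] * xglu[i];
      double gGE = P.g_GABA_E * mGE[i] * xgaba[i];
      rep_step(rE, true, P, gAE, gNE, gGE, VK_E[i], VG_E[i], P.gL_E,
               P.VL_E + P.wK_E * (VK_E[i] - P.VK0_ref), -IpE[i], Ca[i], dt,
               tb_fN);
      double gAI = P.g_AMPA_I * mAI[i] * xglu[i];
      double gNI = P.g_NMDA_I * mNI[i] * xglu[i];
      double gGI = P.g_GABA_I * mGI[i] * xgaba[i];
      rep_step(rI, false, P, gAI, gNI, gGI, VK_I[i], VG_I[i], P.gL_I,
               P.VL_I + P.wK_I * (VK_I[i] - P.VK0_ref), Iou[i] - IpI[i],
               0.0, dt, tb_fN);
    };
    reps(P.s1, repE1, repI1);
    reps(P.s2, repE2, repI2);

    // --- diffusion operator on the current K field ---
    if (P.D1d > 0) {
      for (int i = 0; i < nx; ++i) {
        double fl = (i > 0) ? (K_o[i - 1] - K_o[i]) : 0.0;
        double fr = (i < nx - 1) ? (K_o[i + 1] - K_o[i]) : 0.0;
        lapK[i] = P.D1d * (fl + fr) / (P.dx * P.dx);
      }
    } else {
      std::fill(lapK.begin(), lapK.end(), 0.0);
    }

    // --- ionic balances ---
    for (int i = 0; i < nx; ++i) {
      double gAE = gA_E_x[i] * mAE[i] * xglu[i];
      double gNE = P.g_NMDA_E * mNE[i] * xglu[i];
      double gGE = P.g_GABA_E * mGE[i] * xgaba[i];
      double gAI = P.g_AMPA_I * mAI[i] * xglu[i];
      double gNI = P.g_NMDA_I * mNI[i] * xglu[i];
      double gGI = P.g_GABA_I * mGI[i] * xgaba[i];

      auto intra = [&](bool isE2, double Ub, double nu_, double IKact_,
                       double gAx, double gNx, double gGx, double VK,
                       double VCl, double VNa, double VG, double Ki,
                       double Nai, double &dK, double &dCl, double &dNa) {
        double IKleak = P.g_KL * (Ub - VK);
        double IClleak = P.g_ClL * (Ub - VCl);
        double INaleak = P.g_NaL * (Ub - VNa);
        // influx availability: transmembrane loads collapse as the ECS
        // pool of the carrier ion depletes (spikes need Na driving force;
        // GABA-A chloride entry needs extracellular chloride)
        double navail = Na_o[i] / 40.0;
        if (navail > 1) navail = 1; else if (navail < 0) navail = 0;
        double clavail = Cl_o[i] / 40.0;
        if (clavail > 1) clavail = 1; else if (clavail < 0) clavail = 0;
        double gglu = gAx + gNx * tb_fN.at(Ub);
        double IKglu = P.frac_K_glu * gglu * (Ub - VK);
        double INaglu = P.frac_Na_glu * gglu * (Ub - VNa);
        // chloride flux through GABA-A uses the chloride-only driving
        // force: Cl- enters whenever U > V_Cl even while the total GABA
        // current (reversal V_GABA, carried partly by HCO3-) is inward
        double IGABA = gGx * (Ub - VCl);
        if (IGABA > 0) IGABA *= clavail;
        double Ipump = P.pump_kinetic
                           ? pump_kin(Ub, Ki, K_o[i], Nai, Na_o[i], P.I_pump_max)
                           : pump_sig(K_o[i], Nai, P.I_pump_max);
        if (Ipump < 0) Ipump = 0; // ATP hydrolysis direction only
        if (isE2) IpE[i] = Ipump; else IpI[i] = Ipump;
        double J0K = isE2 ? P.J0K_E : P.J0K_I;
        double J0Na = isE2 ? P.J0Na_E : P.J0Na_I;
        double ukcc = VK - VCl;
        double IKCC2;
        if (P.kcc2_literal) {
          // printed form: imports K+Cl at rest (VK < VCl), exports when
          // [K+]o is elevated (0 < u < 40); pole guarded
          double denk = ukcc - 40.0;
          if (std::fabs(denk) < 1e-6) denk = -1e-6;
          IKCC2 = P.I_KCC2_max * ukcc / denk;
        } else {
          // saturating odd form: extrusion at rest, import under high [K+]o
          IKCC2 = P.I_KCC2_max * ukcc / (std::fabs(ukcc) + 40.0);
        }
        double INKCC1 = isE2 ? 0.0
                             : P.I_NKCC1_max_I * (VNa + VK - 2 * VCl) / P.nernst;
        double INCX = isE2 ? Ca[i] / (P.gamma_ion * P.tau_Ca) : 0.0;
        double g = P.gamma_ion;
        dK = g * (-IKleak - IKact_ - IKglu + 2 * Ipump + IKCC2 + INKCC1 + J0K);
        dCl = g * (IClleak + IGABA + IKCC2 + 2 * INKCC1);
        dNa = g * (-INaleak - INaglu + 1000.0 * P.q_Na * nu_ * navail -
                   3 * Ipump + INKCC1 + INCX + J0Na);
      };
      double dKE, dClE, dNaE, dKI, dClI, dNaI;
      intra(true, E.Ubar[i], E.nu[i], E.IKact[i], gAE, gNE, gGE, VK_E[i],
            VCl_E[i], VNa_E[i], VG_E[i], K_iE[i], Na_iE[i], dKE, dClE, dNaE);
      intra(false, I.Ubar[i], I.nu[i], I.IKact[i], gAI, gNI, gGI, VK_I[i],
            VCl_I[i], VNa_I[i], VG_I[i], K_iI[i], Na_iI[i], dKI, dClI, dNaI);

      // glial buffer
      double G = 0.0;
      if (P.glia_on) {
        double k2 = P.k1_glia /
                    (1 + std::exp(-(K_o[i] - P.K_half_glia) / P.K_slope_glia));
        double dB = P.k1_glia * (P.B_max - Bgl[i]) - k2 * Bgl[i];
        Bgl[i] += dt * dB;
        G = -dB;
      }
      double mixK = -P.beta_vol * ((1 - P.alpha_I) * dKE + P.alpha_I * dKI);
      double mixCl = -P.beta_vol * ((1 - P.alpha_I) * dClE + P.alpha_I * dClI);
      double mixNa = -P.beta_vol * ((1 - P.alpha_I) * dNaE + P.alpha_I * dNaI);
      Wk[i] += dt * (mixK + G + P.D_bath * (P.K_bath - K_o[i]) + lapK[i]);
      Wcl[i] += dt * mixCl;
      Wna[i] += dt * mixNa;
      K_iE[i] += dt * dKE; K_iI[i] += dt * dKI;
      Cl_iE[i] += dt * dClE; Cl_iI[i] += dt * dClI;
      Na_iE[i] += dt * dNaE; Na_iI[i] += dt * dNaI;
      auto fl = [&](double &x) { if (x < 1e-3) { x = 1e-3; ++floor_warnings; } };
      fl(K_iE[i]); fl(K_iI[i]); fl(Cl_iE[i]); fl(Cl_iI[i]);
      fl(Na_iE[i]); fl(Na_iI[i]); fl(Wk[i]); fl(Wcl[i]); fl(Wna[i]);

      // calcium (E only), sign: influx for U below the Ca reversal
      double drive = P.chi_Ca * gNE * tb_fN.at(E.Ubar[i]) *
                     (P.V_Ca - E.Ubar[i]);
      double Cainf = P.tau_Ca * drive;
      Ca[i] = Cainf + (Ca[i] - Cainf) * std::exp(-dt / P.tau_Ca);
      if (Ca[i] < 0) Ca[i] = 0;

      // volume
      if (P.vol_dyn) {
        double sum_i = (1 - P.alpha_I) * (K_iE[i] + Cl_iE[i] + Na_iE[i]) +
                       P.alpha_I * (K_iI[i] + Cl_iI[i] + Na_iI[i]);
        double sum_o = K_o[i] + Cl_o[i] + Na_o[i];
        double dpi = (sum_o - sum_o0) - (sum_i - sum_i0);
        if (dpi > 60) dpi = 60;       // osmotic drive clamp: keeps the
        if (dpi < -60) dpi = -60;     // exp() response in a physical range
        double vinf =
            1 + P.v_gain * P.beta0_v * (std::exp(dpi / P.pi_scale) - 1);
        vol[i] = vinf + (vol[i] - vinf) * std::exp(-dt / P.tau_v);
        if (vol[i] < 0.2) vol[i] = 0.2;
        if (vol[i] > 3.0) vol[i] = 3.0;
      }
      K_o[i] = Wk[i] / vol[i];
      Cl_o[i] = Wcl[i] / vol[i];
      Na_o[i] = Wna[i] / vol[i];
    }

    // --- blow-up guard ---
    if ((step & 1023) == 0) {
      for (int i = 0; i < nx; ++i)
        if (!std::isfinite(K_o[i]) || !std::isfinite(E.Ubar[i]) ||
            !std::isfinite(I.Ubar[i])) {
          blown = true;
          blow_step = step;
          break;
        }
    }

    // --- observables ---
    double t_ms = (step + 1) * dt;
    if ((step + 1) % P.tr_stride == 0 && itr < ntr) {
      int i1 = P.s1, i2 = P.s2;
      double fh = tb_fN.at(-27.0);
      auto hold = [&](int i) {
        double gAEl = gA_E_x[i] * mAE[i] * xglu[i];
        double gNEl = P.g_NMDA_E * mNE[i] * xglu[i];
        double gGEl = P.g_GABA_E * mGE[i] * xgaba[i];
        return gGEl * (-27.0 - VG_E[i]) + gAEl * (-27.0 - P.V_AMPA) +
               gNEl * fh * (-27.0 - P.V_NMDA);
      };
      tr_time[itr] = t_ms / 1000.0;
      traces(itr, 0) = K_o[i1];
      traces(itr, 1) = K_o[i2];
      traces(itr, 2) = E.Ubar[i1];
      traces(itr, 3) = E.Ubar[i2];
      traces(itr, 4) = I.Ubar[i1];
      traces(itr, 5) = I.Ubar[i2];
      traces(itr, 6) = E.nu[i1] * 1000;
      traces(itr, 7) = E.nu[i2] * 1000;
      traces(itr, 8) = I.nu[i1] * 1000;
      traces(itr, 9) = I.nu[i2] * 1000;
      traces(itr, 10) = repE1.V;
      traces(itr, 11) = repE2.V;
      traces(itr, 12) = repI1.V;
      traces(itr, 13) = repI2.V;
      traces(itr, 14) = hold(i1);
      traces(itr, 15) = hold(i2);
      traces(itr, 16) = VG_I[i1];
      traces(itr, 17) = VG_E[i1];
      traces(itr, 18) = xglu[i1];
      traces(itr, 19) = Na_iE[i1];
      traces(itr, 20) = K_iE[i1];
      traces(itr, 21) = Cl_iE[i1];
      traces(itr, 22) = Cl_iI[i1];
      traces(itr, 23) = K_iI[i1];
      traces(itr, 24) = Cl_o[i1];
      traces(itr, 25) = Na_o[i1];
      traces(itr, 26) = vol[i1];
      traces(itr, 27) = Ca[i1];
      ++itr;
    }
    if ((step + 1) % P.fd_stride == 0 && ifd < nfd) {
      fd_time[ifd] = t_ms / 1000.0;
      for (int i = 0; i < nx; ++i) {
        fUE(ifd, i) = E.Ubar[i];
        fKo(ifd, i) = K_o[i];
        fClE(ifd, i) = Cl_iE[i];
        fNaE(ifd, i) = Na_iE[i];
        fvol(ifd, i) = vol[i];
        fnuE(ifd, i) = E.nu[i] * 1000;
        fnuI(ifd, i) = I.nu[i] * 1000;
      }
      ++ifd;
    }
  }

  CharacterVector trnames = CharacterVector::create(
      "K_o_S1", "K_o_S2", "U_E_S1", "U_E_S2", "U_I_S1", "U_I_S2", "nu_E_S1",
      "nu_E_S2", "nu_I_S1", "nu_I_S2", "V_repE_S1", "V_repE_S2", "V_repI_S1",
      "V_repI_S2", "I_hold_S1", "I_hold_S2", "V_GABA_I_S1", "V_GABA_E_S1",
      "x_glu_S1", "Na_iE_S1", "K_iE_S1", "Cl_iE_S1", "Cl_iI_S1",
      "K_iI_S1", "Cl_o_S1", "Na_o_S1", "vol_S1", "Ca_S1");

  return List::create(
      _["trace_time_s"] = tr_time[Range(0, std::max(itr - 1, 0))],
      _["traces"] = traces(Range(0, std::max(itr - 1, 0)), _),
      _["trace_names"] = trnames,
      _["field_time_s"] = fd_time[Range(0, std::max(ifd - 1, 0))],
      _["U_E"] = fUE(Range(0, std::max(ifd - 1, 0)), _),
      _["K_o"] = fKo(Range(0, std::max(ifd - 1, 0)), _),
      _["Cl_iE"] = fClE(Range(0, std::max(ifd - 1, 0)), _),
      _["Na_iE"] = fNaE(Range(0, std::max(ifd - 1, 0)), _),
      _["vol"] = fvol(Range(0, std::max(ifd - 1, 0)), _),
      _["nu_E"] = fnuE(Range(0, std::max(ifd - 1, 0)), _),
      _["nu_I"] = fnuI(Range(0, std::max(ifd - 1, 0)), _),
      _["mass_dev_max"] = mass_dev_max,
      _["floor_warnings"] = floor_warnings,
      _["nM_reset"] = P.nM_reset,
      _["J0"] = NumericVector::create(P.J0K_E, P.J0Na_E, P.J0K_I, P.J0Na_I),
      _["U0_E"] = U0E, _["U0_I"] = U0I,
      _["blown"] = blown, _["blow_step"] = blow_step);
}

// ------------------------------------- single-population CBRD runner ----
// Uncoupled population with frozen ionic concentrations, driven by a step
// current; used to validate the density approximation against the
// Monte-Carlo ensemble.
// [[Rcpp::export]]
List cpp_cbrd_single(List pl, double duration_ms, double dt, double tstar_max,
                     double I_step, double t_on, bool isE,
                     double sigma_V0_over) {
  Par P;
  P.C = getd(pl, "C");
  P.g_DR = getd(pl, "g_DR");
  P.g_M_E = getd(pl, "g_M_E");
  P.g_KCa_E = getd(pl, "g_KCa_E");
  P.g_KL = getd(pl, "g_KL");
  P.g_ClL = getd(pl, "g_ClL");
  P.g_NaL = getd(pl, "g_NaL");
  P.V_reset = getd(pl, "V_reset");
  P.dt_AP = getd(pl, "dt_AP");
  P.n_DR_reset = getd(pl, "n_DR_reset");
  P.V_DB = getd(pl, "V_DB");
  P.DB_amp = getd(pl, "DB_amp");
  P.tau_Uinf = getd(pl, "tau_Uinf");
  P.sigma_V0 = sigma_V0_over > 0 ? sigma_V0_over : getd(pl, "sigma_V0");
  P.tau_Noise = getd(pl, "tau_Noise");
  P.Mg = getd(pl, "Mg");
  P.g_Na_rep = getd(pl, "g_Na_rep");
  P.g_DR_rep = getd(pl, "g_DR_rep");
  P.V_Na_rep = getd(pl, "V_Na_rep");
  P.alpha_KCa = getd(pl, "alpha_KCa");
  P.beta_KCa = getd(pl, "beta_KCa");
  P.V_L = getd(pl, "V_L");
  double Vth0 = isE ? getd(pl, "V_th0_E") : getd(pl, "V_th0_I");
  double K_i0 = getd(pl, "K_i0"), K_o0 = getd(pl, "K_o0");
  double nernst = getd(pl, "nernst_mV");
  double VK = nernst * std::log(K_o0 / K_i0);
  double tau_m0 = isE ? getd(pl, "tau_m0_E") : getd(pl, "tau_m0_I");
  double aa = aDR(P.V_L), bb = bDR(P.V_L);
  double nDR0r = aa / (aa + bb);
  aa = aM(P.V_L); bb = bM(P.V_L);
  double gvg0 = P.g_DR * std::pow(nDR0r, 4) +
                (isE ? P.g_M_E * aa / (aa + bb) : 0.0);
  double gpass = P.C / tau_m0;
  double gL = std::max(1e-4, gpass - gvg0);
  double VLp = P.V_L + (gvg0 / gL) * (P.V_L - VK);
  double U0 = P.V_L;
  P.nM_reset = compute_nM_reset(P, VK, gL);
  P.dt = dt;
  int nb = (int)std::round(tstar_max / dt);
  P.jfroz = (int)std::ceil(P.dt_AP / dt) - 1;

  GateTabCtx gtc{dt};
  Tab1 tb_ninfDR, tb_edecDR, tb_ninfM, tb_edecM, tb_sig, tb_expg, tb_B;
  tb_ninfDR.build(-150, 80, 4601, ninfDR, nullptr);
  tb_edecDR.build(-150, 80, 4601, edecDR, &gtc);
  tb_ninfM.build(-150, 80, 4601, ninfM, nullptr);
  tb_edecM.build(-150, 80, 4601, edecM, &gtc);
  tb_sig.build(-150, 80, 4601, sigDB, nullptr);
  tb_expg.build(0, 25, 12501, expg_, &gtc);
  tb_B.build(-8, 8, 3201, btab_, nullptr);
  HazTab tb_A;
  tb_A.build();

  Pop pop;
  pop.init(1, nb, U0, isE, dt);
  const double sq2 = std::sqrt(2.0), twoosqpi = 2.0 / std::sqrt(M_PI);
  const double eU = std::exp(-dt / P.tau_Uinf);
  int nsteps = (int)std::round(duration_ms / dt);
  NumericVector nu_out(nsteps), mass_out(nsteps);

  double *rho = &pop.rho[0], *U = &pop.U[0], *nDR = &pop.nDR[0],
         *nM = &pop.nM[0], *nKCa = &pop.nKCa[0], *Uinf = &pop.Uinf[0],
         *Tprev = &pop.Tprev[0];
  double gM = isE ? P.g_M_E : 0.0;
  for (int step = 0; step < nsteps; ++step) {
    double Iext = (step * dt >= t_on) ? I_step : 0.0;
    int lo = pop.act_lo[0];
    if (lo <= nb - 2) {
      double ra = rho[nb - 1], rb = rho[nb - 2], s = ra + rb;
      if (s > 0) {
        double wa = ra / s, wb = rb / s;
        U[nb - 1] = wa * U[nb - 1] + wb * U[nb - 2];
        nDR[nb - 1] = wa * nDR[nb - 1] + wb * nDR[nb - 2];
        nM[nb - 1] = wa * nM[nb - 1] + wb * nM[nb - 2];
        nKCa[nb - 1] = wa * nKCa[nb - 1] + wb * nKCa[nb - 2];
        Uinf[nb - 1] = wa * Uinf[nb - 1] + wb * Uinf[nb - 2];
        Tprev[nb - 1] = wa * Tprev[nb - 1] + wb * Tprev[nb - 2];
      }
      rho[nb - 1] = s;
      for (int j = nb - 2; j > lo; --j) {
        rho[j] = rho[j - 1]; U[j] = U[j - 1]; nDR[j] = nDR[j - 1];
        nM[j] = nM[j - 1]; nKCa[j] = nKCa[j - 1]; Uinf[j] = Uinf[j - 1];
        Tprev[j] = Tprev[j - 1];
      }
      rho[lo] = 0.0;
      if (lo < nb - 1) pop.act_lo[0] = ++lo;
    }
    double inj = pop.nu[0];
    if (inj > 1e-7) {
      rho[0] = inj;
      nKCa[0] = pop.nKCa_tp[0];
      Uinf[0] = pop.Uinf_tp[0];
      lo = 0;
      pop.act_lo[0] = 0;
    } else if (inj > 0) {
      rho[nb - 1] += inj;
    }
    double removed = 0, massacc = 0;
    double relmax = -1; int jrel = nb - 1;
    for (int j = lo; j < nb; ++j) {
      if (j <= P.jfroz) {
        if (rho[j] < 1e-8) { massacc += rho[j]; continue; }
        U[j] = P.V_reset;
        nDR[j] = P.n_DR_reset;
        if (isE) nM[j] = P.nM_reset;
        Uinf[j] += (P.V_reset - Uinf[j]) * (1 - eU);
        massacc += rho[j];
        continue;
      }
      if (rho[j] < 1e-8 && j != nb - 1) { massacc += rho[j]; continue; }
      double Uj = U[j];
      double ni = tb_ninfDR.at(Uj), ed = tb_edecDR.at(Uj);
      nDR[j] = ni + (nDR[j] - ni) * ed;
      if (isE) {
        ni = tb_ninfM.at(Uj); ed = tb_edecM.at(Uj);
        nM[j] = ni + (nM[j] - ni) * ed;
      }
      double n2 = nDR[j] * nDR[j];
      double gvg = P.g_DR * n2 * n2 + gM * nM[j];
      double gtot = gL + gvg;
      double num = gL * VLp + gvg * VK + Iext;
      double Ueq = num / gtot;
      double Un = Ueq + (Uj - Ueq) * tb_expg.at(gtot);
      U[j] = Un;
      Uinf[j] += (Un - Uinf[j]) * (1 - eU);
      double Vth = Vth0 + P.DB_amp * tb_sig.at(Uinf[j]);
      double sV = P.sigma_V0;
      double T = (Vth - Un) / (sq2 * sV);
      double dTdt = (T - Tprev[j]) / dt;
      Tprev[j] = T;
      double k = P.C / (gtot * P.tau_Noise);
      double A = tb_A.at(T, k) * gtot / P.C;
      double Bt = 0;
      if (dTdt < 0) {
        double bs = (T < -8) ? bshape(T) : tb_B.at(T);
        Bt = twoosqpi * (-dTdt) * bs;
      }
      double f = (A + Bt) * dt;
      double dec = (f < 0.01) ? 1 - f * (1 - 0.5 * f * (1 - f / 3))
                              : std::exp(-f);
      double rem = rho[j] * (1 - dec);
      removed += rem;
      rho[j] *= dec;
      double rel = rho[j] * (A + Bt);
      if (rel > relmax) { relmax = rel; jrel = j; }
      massacc += rho[j];
    }
    pop.nu[0] = removed;
    pop.nKCa_tp[0] = nKCa[jrel];
    pop.Uinf_tp[0] = Uinf[jrel];
    nu_out[step] = removed * 1000.0; // Hz
    mass_out[step] = (massacc + removed) * dt;
  }
  return List::create(_["nu_Hz"] = nu_out, _["mass"] = mass_out,
                      _["U0"] = U0);
}

// ------------------------------------------ Monte-Carlo ensemble oracle ----
// N individual neurons with the population's membrane equations, a shared
// step input and per-neuron colored voltage noise; spikes are threshold
// crossings of U + eta with the same dynamic-threshold rule, followed by
// the same reset/refractory convention. Ion concentrations frozen at rest.
// [[Rcpp::export]]
List cpp_mc_population(List pl, int N, double duration_ms, double dt,
                       double I_step, double t_on, bool isE, double seed,
                       double bin_ms, double sigma_V0_over) {
  double C = getd(pl, "C");
  double g_DR = getd(pl, "g_DR");
  double g_M = isE ? getd(pl, "g_M_E") : 0.0;
  double V_L = getd(pl, "V_L");
  double V_reset = getd(pl, "V_reset"), dt_AP = getd(pl, "dt_AP");
  double n_DR_reset = getd(pl, "n_DR_reset");
  double DB_amp = getd(pl, "DB_amp"), tau_Uinf = getd(pl, "tau_Uinf");
  double sigma_V0 = sigma_V0_over > 0 ? sigma_V0_over : getd(pl, "sigma_V0");
  double tau_Noise = getd(pl, "tau_Noise");
  double Vth0 = isE ? getd(pl, "V_th0_E") : getd(pl, "V_th0_I");
  double K_i0 = getd(pl, "K_i0"), K_o0 = getd(pl, "K_o0");
  double nernst = getd(pl, "nernst_mV");
  double VK = nernst * std::log(K_o0 / K_i0);
  double tau_m0 = isE ? getd(pl, "tau_m0_E") : getd(pl, "tau_m0_I");
  double aa0 = aDR(V_L), bb0 = bDR(V_L);
  double nDR0r = aa0 / (aa0 + bb0);
  aa0 = aM(V_L); bb0 = bM(V_L);
  double gvg0 = g_DR * std::pow(nDR0r, 4) + (isE ? g_M * aa0 / (aa0 + bb0) : 0.0);
  double gpass = getd(pl, "C") / tau_m0;
  double gL = std::max(1e-4, gpass - gvg0);
  double VLp = V_L + (gvg0 / gL) * (V_L - VK);
  double U0 = V_L;
  double V_DB = getd(pl, "V_DB"), DB_slope = getd(pl, "DB_slope");

  // nM reset for consistency with the density model
  Par Ptmp;
  Ptmp.C = C; Ptmp.g_DR = g_DR; Ptmp.g_M_E = getd(pl, "g_M_E");
  Ptmp.g_KCa_E = getd(pl, "g_KCa_E");
  Ptmp.g_Na_rep = getd(pl, "g_Na_rep"); Ptmp.g_DR_rep = getd(pl, "g_DR_rep");
  Ptmp.V_Na_rep = getd(pl, "V_Na_rep");
  Ptmp.V_L = V_L; Ptmp.V_AMPA = 0; Ptmp.V_NMDA = 0; Ptmp.Mg = getd(pl, "Mg");
  Ptmp.alpha_KCa = getd(pl, "alpha_KCa"); Ptmp.beta_KCa = getd(pl, "beta_KCa");
  double nM_reset = compute_nM_reset(Ptmp, VK, gL);

  int nsteps = (int)std::round(duration_ms / dt);
  int binw = (int)std::round(bin_ms / dt);
  int nbins = nsteps / binw;
  NumericVector rate(nbins);

  double ou_a = std::exp(-dt / tau_Noise);
  double ou_b = std::sqrt(1 - ou_a * ou_a);
  double a0 = aDR(U0), b0 = bDR(U0);
  double nDR0 = a0 / (a0 + b0);
  double aM0 = aM(U0), bM0 = bM(U0);
  double nM0 = isE ? aM0 / (aM0 + bM0) : 0.0;

  std::vector<double> U(N, U0), nDR(N, nDR0), nM(N, nM0), Uinf(N, U0),
      eta(N), tsls(N, 1e9);
  Rng r;
  r.seed((uint64_t)seed, 9001);
  for (int n = 0; n < N; ++n) eta[n] = r.gauss();

  for (int step = 0; step < nsteps; ++step) {
    double Iext = (step * dt >= t_on) ? I_step : 0.0;
    int bin = step / binw;
    for (int n = 0; n < N; ++n) {
      eta[n] = eta[n] * ou_a + ou_b * r.gauss();
      if (tsls[n] < dt_AP) { // frozen spike window: same semantics as
        tsls[n] += dt;        // the density model's reset bins
        U[n] = V_reset;
        nDR[n] = n_DR_reset;
        if (isE) nM[n] = nM_reset;
        Uinf[n] += (V_reset - Uinf[n]) * (1 - std::exp(-dt / tau_Uinf));
        continue;
      }
      double a = aDR(U[n]), b = bDR(U[n]), rr = a + b;
      nDR[n] = a / rr + (nDR[n] - a / rr) * std::exp(-rr * dt);
      if (isE) {
        a = aM(U[n]); b = bM(U[n]); rr = a + b;
        nM[n] = a / rr + (nM[n] - a / rr) * std::exp(-rr * dt);
      }
      double n2 = nDR[n] * nDR[n];
      double gvg = g_DR * n2 * n2 + g_M * nM[n];
      double gtot = gL + gvg;
      double num = gL * VLp + gvg * VK + Iext;
      double Ueq = num / gtot;
      U[n] = Ueq + (U[n] - Ueq) * std::exp(-gtot * dt / C);
      Uinf[n] += (U[n] - Uinf[n]) * (1 - std::exp(-dt / tau_Uinf));
      double Vth =
          Vth0 + DB_amp / (1 + std::exp(-(Uinf[n] - V_DB) / DB_slope));
      double sV = sigma_V0;
      if (U[n] + eta[n] * sV >= Vth) {
        tsls[n] = 0.0;
        U[n] = V_reset;
        nDR[n] = n_DR_reset;
        if (isE) nM[n] = nM_reset;
        if (bin < nbins) rate[bin] += 1.0;
      }
    }
  }
  for (int b = 0; b < nbins; ++b) rate[b] = rate[b] / N / (bin_ms / 1000.0);
  NumericVector tc(nbins);
  for (int b = 0; b < nbins; ++b) tc[b] = (b + 0.5) * bin_ms;
  return List::create(_["t_ms"] = tc, _["rate_Hz"] = rate, _["U0"] = U0);
}

// OU noise reference step (exported for direct testing of the exact
// update used by the engine)
// [[Rcpp::export]]
NumericVector cpp_ou_trace(int n, double dt, double tau, double sd,
                           double seed, int stream) {
  Rng r;
  r.seed((uint64_t)seed, (uint64_t)stream);
  double a = std::exp(-dt / tau), b = sd * std::sqrt(1 - a * a);
  NumericVector out(n);
  double x = 0;
  for (int i = 0; i < n; ++i) {
    x = x * a + b * r.gauss();
    out[i] = x;
  }
  return out;
}
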