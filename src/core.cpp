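#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Compiled regulatory inputs of one gene copy: source protein types of its
// activating and repressing binding sites. Type-0 gene copies are inert
// (the morphogen is clamped by the tissue, not transcribed).
// Compiled genome: per-gene site lists flattened into contiguous arrays
// (activating sites first, then repressing), and the list of protein types
// referenced by at least one functional site. Type-0 gene copies are inert
// (the morphogen is clamped by the tissue, not transcribed).
struct Circuit {
  int n_genes;
  std::vector<int> type;      // gene type per gene
  std::vector<int> act_start, act_end, rep_end; // ranges into `site`
  std::vector<int> site;      // source types, activators then repressors
  std::vector<int> used;      // distinct referenced types
  int n_used;
};

static Circuit compile_genome(const IntegerVector& gene_types,
                              const IntegerVector& site_gene,
                              const IntegerVector& site_type,
                              const IntegerVector& site_weight) {
  Circuit c;
  int ng = gene_types.size();
  c.n_genes = ng;
  c.type.assign(gene_types.begin(), gene_types.end());
  c.act_start.resize(ng); c.act_end.resize(ng); c.rep_end.resize(ng);
  bool used[16] = {false};
  for (int g = 0; g < ng; ++g) {
    c.act_start[g] = (int)c.site.size();
    for (int s = 0; s < site_gene.size(); ++s)
      if (site_gene[s] - 1 == g && c.type[g] != 0 && site_weight[s] > 0) {
        c.site.push_back(site_type[s]);
        used[site_type[s]] = true;
      }
    c.act_end[g] = (int)c.site.size();
    for (int s = 0; s < site_gene.size(); ++s)
      if (site_gene[s] - 1 == g && c.type[g] != 0 && site_weight[s] < 0) {
        c.site.push_back(site_type[s]);
        used[site_type[s]] = true;
      }
    c.rep_end[g] = (int)c.site.size();
  }
  for (int t = 0; t < 16; ++t) if (used[t]) c.used.push_back(t);
  c.n_used = (int)c.used.size();
  return c;
}

// One Euler update of the non-morphogen proteins of a single cell.
// conc points at 16 doubles. The Hill terms of every referenced regulator
// type are computed once per cell-step (activation and repression share
// one reciprocal, with the divisions batched so they pipeline). Consumes
// one norm_rand() per non-type-0 gene copy when noise_l > 0 (even when the
// expected rate is 0), matching the R reference stepper draw-for-draw.
static inline void step_cell_core(double* conc, const Circuit& cir,
                                  double E, double delta, double Hn, double n,
                                  double dt, double noise_l) {
  if (noise_l == 0.0) {
    // an all-zero cell is a fixed point (no basal transcription); head
    // cells stay on this branch for the whole of development
    bool allzero = true;
    for (int t = 0; t < 16; ++t) if (conc[t] > 0.0) { allzero = false; break; }
    if (allzero) return;
  }
  double den[16], inv[16], act16[16], rep16[16];
  const int nu = cir.n_used;
  for (int i = 0; i < nu; ++i) {
    double x = conc[cir.used[i]];
    double xn = (n == 2.0) ? x * x : (x > 0.0 ? std::pow(x, n) : 0.0);
    act16[i] = xn;          // numerator, scaled below
    den[i] = xn + Hn;
  }
  for (int i = 0; i < nu; ++i) inv[i] = 1.0 / den[i];
  double hill_a[16], hill_r[16];
  for (int i = 0; i < nu; ++i) {
    hill_a[cir.used[i]] = act16[i] * inv[i];
    hill_r[cir.used[i]] = Hn * inv[i];
  }
  (void)rep16;
  double prod[16] = {0.0};
  for (int g = 0; g < cir.n_genes; ++g) {
    const int tg = cir.type[g];
    if (tg == 0) continue;
    double rate = 0.0;
    const int a0 = cir.act_start[g], a1 = cir.act_end[g], r1 = cir.rep_end[g];
    if (a1 > a0) {
      double a = 0.0;
      for (int j = a0; j < a1; ++j) {
        double t = hill_a[cir.site[j]];
        if (t > a) a = t;
      }
      if (a > 0.0) {
        double rp = 1.0;
        for (int k = a1; k < r1; ++k) rp *= hill_r[cir.site[k]];
        rate = a * rp * E;
      }
    }
    if (noise_l > 0.0) {
      rate += noise_l * rate * norm_rand();
      if (rate < 0.0) rate = 0.0;
    }
    prod[tg] += rate;
  }
  for (int t = 1; t < 16; ++t) {
    conc[t] += dt * (prod[t] - delta * conc[t]);
    if (conc[t] < 0.0) conc[t] = 0.0;
  }
}

// Full developmental run of one embryo: growth from a posterior growth zone,
// morphogen clamped in the zone and decaying outside it, forward Euler
// dynamics in every cell. Cells are stored anterior -> posterior.
// [[Rcpp::export]]
List develop_cpp(IntegerVector gene_types, IntegerVector site_gene,
                 IntegerVector site_type, IntegerVector site_weight,
                 int n_steps, int n_growth, int div_interval,
                 int n_head, int n_zone,
                 double E, double delta, double H, double n_hill, double dt,
                 double d_decay, double M_max, double noise_l,
                 int record_last, bool record_full) {
  RNGScope rng;
  Circuit cir = compile_genome(gene_types, site_gene, site_type, site_weight);
  double Hn = (n_hill == 2.0) ? H * H : std::pow(H, n_hill);
  double decay_factor = 1.0 - d_decay * dt;
  if (decay_factor < 0.0) decay_factor = 0.0;

  int n0 = n_head + n_zone;
  int n_div = (div_interval > 0) ? n_growth / div_interval : 0;
  int n_final = n0 + n_div;

  std::vector<double> conc((size_t)n_final * 16, 0.0);
  int n_cells = n0;
  for (int i = n_cells - n_zone; i < n_cells; ++i) conc[(size_t)i * 16] = M_max;

  IntegerVector birth_step(n_final, NA_INTEGER);
  for (int i = 0; i < n_head; ++i) birth_step[i] = 0;

  NumericMatrix seg_record(n_final, record_last > 0 ? record_last : 0);
  if (record_last > 0) std::fill(seg_record.begin(), seg_record.end(), NA_REAL);
  NumericMatrix full_record;
  if (record_full) {
    full_record = NumericMatrix(n_final, n_steps);
    std::fill(full_record.begin(), full_record.end(), NA_REAL);
  }

  if (noise_l == 0.0) {
    // Deterministic fast path: one array per protein type (structure of
    // arrays), so Hill terms, OR-gate maxima, AND-gate products and the
    // Euler update all vectorise across cells.
    const int nf = n_final;
    const int nu = cir.n_used;
    std::vector<double> C((size_t)16 * nf, 0.0);
    for (int i = n_cells - n_zone; i < n_cells; ++i) C[i] = M_max;
    for (int i = 0; i < n_cells; ++i) conc[(size_t)i * 16] = 0.0; // unused in this path
    std::vector<double> hillA((size_t)std::max(nu, 1) * nf),
                        hillR((size_t)std::max(nu, 1) * nf),
                        rate(nf), prodv((size_t)16 * nf);
    int uidx[16];
    for (int t = 0; t < 16; ++t) uidx[t] = -1;
    for (int u = 0; u < nu; ++u) uidx[cir.used[u]] = u;

    for (int s = 1; s <= n_steps; ++s) {
      double* M = &C[0];
      for (int i = 0; i < n_cells - n_zone; ++i) M[i] *= decay_factor;
      for (int i = n_cells - n_zone; i < n_cells; ++i) M[i] = M_max;
      for (int u = 0; u < nu; ++u) {
        const double* __restrict__ x = &C[(size_t)cir.used[u] * nf];
        double* __restrict__ ha = &hillA[(size_t)u * nf];
        double* __restrict__ hr = &hillR[(size_t)u * nf];
        if (n_hill == 2.0) {
          for (int i = 0; i < n_cells; ++i) {
            double xn = x[i] * x[i];
            double inv = 1.0 / (xn + Hn);
            ha[i] = xn * inv;
            hr[i] = Hn * inv;
          }
        } else {
          for (int i = 0; i < n_cells; ++i) {
            double xn = x[i] > 0.0 ? std::pow(x[i], n_hill) : 0.0;
            double inv = 1.0 / (xn + Hn);
            ha[i] = xn * inv;
            hr[i] = Hn * inv;
          }
        }
      }
      std::fill(prodv.begin(), prodv.end(), 0.0);
      for (int g = 0; g < cir.n_genes; ++g) {
        const int tg = cir.type[g];
        if (tg == 0) continue;
        const int a0 = cir.act_start[g], a1 = cir.act_end[g], r1 = cir.rep_end[g];
        if (a1 <= a0) continue; // no activators: silent gene
        double* __restrict__ rt = rate.data();
        {
          const double* __restrict__ ha = &hillA[(size_t)uidx[cir.site[a0]] * nf];
          for (int i = 0; i < n_cells; ++i) rt[i] = ha[i];
        }
        for (int j = a0 + 1; j < a1; ++j) {
          const double* __restrict__ ha = &hillA[(size_t)uidx[cir.site[j]] * nf];
          for (int i = 0; i < n_cells; ++i) if (ha[i] > rt[i]) rt[i] = ha[i];
        }
        for (int k = a1; k < r1; ++k) {
          const double* __restrict__ hr = &hillR[(size_t)uidx[cir.site[k]] * nf];
          for (int i = 0; i < n_cells; ++i) rt[i] *= hr[i];
        }
        double* __restrict__ p = &prodv[(size_t)tg * nf];
        for (int i = 0; i < n_cells; ++i) p[i] += rt[i] * E;
      }
      for (int t = 1; t < 16; ++t) {
        double* __restrict__ ct = &C[(size_t)t * nf];
        const double* __restrict__ p = &prodv[(size_t)t * nf];
        for (int i = 0; i < n_cells; ++i) {
          double v = ct[i] + dt * (p[i] - delta * ct[i]);
          ct[i] = v < 0.0 ? 0.0 : v;
        }
      }
      if (div_interval > 0 && s <= n_growth && s % div_interval == 0 && n_cells < n_final) {
        for (int t = 0; t < 16; ++t)
          C[(size_t)t * nf + n_cells] = C[(size_t)t * nf + n_cells - 1];
        ++n_cells;
        birth_step[n_cells - 1 - n_zone] = s;
      }
      if (record_last > 0 && s > n_steps - record_last) {
        int col = s - (n_steps - record_last) - 1;
        const double* c5 = &C[(size_t)5 * nf];
        for (int i = 0; i < n_cells; ++i) seg_record(i, col) = c5[i];
      }
      if (record_full) {
        const double* c5 = &C[(size_t)5 * nf];
        for (int i = 0; i < n_cells; ++i) full_record(i, s - 1) = c5[i];
      }
    }
    NumericMatrix final_conc(n_cells, 16);
    for (int i = 0; i < n_cells; ++i)
      for (int t = 0; t < 16; ++t) final_conc(i, t) = C[(size_t)t * nf + i];
    return List::create(_["conc"] = final_conc,
                        _["seg_record"] = seg_record,
                        _["full_record"] = record_full ? (SEXP)full_record : R_NilValue,
                        _["birth_step"] = birth_step,
                        _["n_cells"] = n_cells);
  }

  for (int s = 1; s <= n_steps; ++s) {
    // morphogen: clamp in the growth zone, discrete exponential decay outside
    for (int i = 0; i < n_cells - n_zone; ++i) conc[(size_t)i * 16] *= decay_factor;
    for (int i = n_cells - n_zone; i < n_cells; ++i) conc[(size_t)i * 16] = M_max;
    // gene expression in every cell
    for (int i = 0; i < n_cells; ++i)
      step_cell_core(&conc[(size_t)i * 16], cir, E, delta, Hn, n_hill, dt, noise_l);
    // division of the posterior-most cell during the growth phase
    if (div_interval > 0 && s <= n_growth && s % div_interval == 0 && n_cells < n_final) {
      for (int t = 0; t < 16; ++t)
        conc[(size_t)n_cells * 16 + t] = conc[(size_t)(n_cells - 1) * 16 + t];
      ++n_cells;
      birth_step[n_cells - 1 - n_zone] = s; // this cell just left the zone
    }
    if (record_last > 0 && s > n_steps - record_last) {
      int col = s - (n_steps - record_last) - 1;
      for (int i = 0; i < n_cells; ++i) seg_record(i, col) = conc[(size_t)i * 16 + 5];
    }
    if (record_full) {
      for (int i = 0; i < n_cells; ++i) full_record(i, s - 1) = conc[(size_t)i * 16 + 5];
    }
  }

  NumericMatrix final_conc(n_cells, 16);
  for (int i = 0; i < n_cells; ++i)
    for (int t = 0; t < 16; ++t) final_conc(i, t) = conc[(size_t)i * 16 + t];

  return List::create(_["conc"] = final_conc,
                      _["seg_record"] = seg_record,
                      _["full_record"] = record_full ? (SEXP)full_record : R_NilValue,
                      _["birth_step"] = birth_step,
                      _["n_cells"] = n_cells);
}

// Single cell with the morphogen clamped at a fixed level; returns the full
// trajectory (one row per step, post-update) of all 16 protein types.
// [[Rcpp::export]]
NumericMatrix simulate_cell_cpp(IntegerVector gene_types, IntegerVector site_gene,
                                IntegerVector site_type, IntegerVector site_weight,
                                double level, int n_steps,
                                double E, double delta, double H, double n_hill,
                                double dt, double noise_l,
                                NumericVector init) {
  RNGScope rng;
  Circuit cir = compile_genome(gene_types, site_gene, site_type, site_weight);
  double Hn = (n_hill == 2.0) ? H * H : std::pow(H, n_hill);
  double conc[16];
  for (int t = 0; t < 16; ++t) conc[t] = init[t];
  conc[0] = level;
  NumericMatrix out(n_steps, 16);
  for (int s = 0; s < n_steps; ++s) {
    conc[0] = level;
    step_cell_core(conc, cir, E, delta, Hn, n_hill, dt, noise_l);
    for (int t = 0; t < 16; ++t) out(s, t) = conc[t];
  }
  return out;
}
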