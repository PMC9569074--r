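#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Individual-based, age-structured forward simulator of a founding
// bottleneck followed by drift under logistic growth with completely
// overlapping generations, plus a discrete-generation (Wright-Fisher)
// constant-size mode used for calibration checks.
//
// Conventions:
//  - alleles are integer codes 1..K_l per locus; no mutation, so allele
//    identities are conserved;
//  - the logistic size trajectory is a precomputed schedule anchored at the
//    founder size, N*_{y+1} = round(N*_y + (lambda-1) N*_y (1 - N*_y/K)):
//    the yearly target does not track the realized census, so recruitment
//    shortfalls are made up in later years (schedule pull-back);
//  - yearly cycle: survivors age by one and die past the lifespan, and
//    births = max(0, N*_y - survivors) are capped at fecundity x (mature
//    females); each newborn draws a uniform mature mother and father and
//    inherits one uniformly chosen allele per locus from each;
//  - statistics are recorded after survival + reproduction; year 0 is the
//    founder state; extinction is recorded when the census reaches zero.

static inline int runif_int(int n) {
  int v = (int)(unif_rand() * n);
  return v >= n ? n - 1 : v;
}

struct FreqTables {
  int L;
  std::vector<int> K;
  std::vector<std::vector<double> > cum;
};

static int draw_allele(const std::vector<double>& cum) {
  double u = unif_rand();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (u <= cum[mid]) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// [[Rcpp::export]]
List run_scenario_cpp(List allele_freqs, int founder_size, int n_females,
                      int n_males, int pre_bottleneck, int lifespan,
                      int mat_age, double lambda, double capacity, int years,
                      int iterations, int fecundity, bool discrete_gens,
                      bool return_genotypes) {
  FreqTables ft;
  ft.L = allele_freqs.size();
  ft.K.resize(ft.L);
  ft.cum.resize(ft.L);
  for (int l = 0; l < ft.L; ++l) {
    NumericVector f = allele_freqs[l];
    ft.K[l] = f.size();
    ft.cum[l].resize(ft.K[l]);
    double s = 0.0;
    for (int a = 0; a < ft.K[l]; ++a) { s += f[a]; ft.cum[l][a] = s; }
    ft.cum[l][ft.K[l] - 1] = 1.0;
  }
  const int L = ft.L;
  const int G = 2 * L;
  const int ny = years + 1;

  IntegerMatrix census(ny, iterations);
  NumericMatrix na_mat(ny, iterations);
  NumericMatrix het_mat(ny, iterations);
  IntegerVector extinct_year(iterations, NA_INTEGER);
  List terminal(return_genotypes ? iterations : 0);

  // deterministic logistic schedule anchored at the founder size
  std::vector<int> sched(ny);
  sched[0] = founder_size;
  for (int y = 1; y < ny; ++y) {
    double N = sched[y - 1];
    sched[y] = (int)std::lround(N + (lambda - 1.0) * N *
                                (1.0 - N / capacity));
  }

  std::vector<int> age, sex;       // sex: 0 female, 1 male
  std::vector<int> geno;           // N x 2L, row-major
  std::vector<int> matF, matM;
  std::vector<std::vector<int> > cnt(L);
  std::vector<int> ndist(L);

  for (int it = 0; it < iterations; ++it) {
    // pre-bottleneck pool, founders sampled without replacement
    std::vector<int> pool((size_t)pre_bottleneck * G);
    for (int i = 0; i < pre_bottleneck; ++i)
      for (int l = 0; l < L; ++l) {
        pool[(size_t)i * G + 2 * l] = draw_allele(ft.cum[l]);
        pool[(size_t)i * G + 2 * l + 1] = draw_allele(ft.cum[l]);
      }
    std::vector<int> idx(pre_bottleneck);
    for (int i = 0; i < pre_bottleneck; ++i) idx[i] = i;
    for (int i = 0; i < founder_size; ++i) {
      int j = i + runif_int(pre_bottleneck - i);
      std::swap(idx[i], idx[j]);
    }
    int N = founder_size;
    age.assign(N, 0);
    sex.assign(N, 1);
    geno.assign((size_t)N * G, 0);
    for (int i = 0; i < N; ++i) {
      for (int g = 0; g < G; ++g)
        geno[(size_t)i * G + g] = pool[(size_t)idx[i] * G + g];
      sex[i] = (i < n_females) ? 0 : 1;
      age[i] = discrete_gens ? mat_age : 1 + runif_int(lifespan - 1);
    }
    for (int l = 0; l < L; ++l) {
      cnt[l].assign(ft.K[l], 0);
      ndist[l] = 0;
    }
    for (int i = 0; i < N; ++i)
      for (int l = 0; l < L; ++l)
        for (int c = 0; c < 2; ++c) {
          int a = geno[(size_t)i * G + 2 * l + c];
          if (cnt[l][a]++ == 0) ndist[l]++;
        }

    // record year y statistics from current counts
    int ext = NA_INTEGER;
    for (int y = 0; y <= years; ++y) {
      if (y > 0) {
        if (N == 0) {
          census(y, it) = 0;
          na_mat(y, it) = NA_REAL;
          het_mat(y, it) = NA_REAL;
          continue;
        }
        int Nstar = discrete_gens ? founder_size : sched[y];
        if (discrete_gens) {
          // Wright-Fisher replacement: previous generation are the parents
          matF.clear(); matM.clear();
          for (int i = 0; i < N; ++i)
            (sex[i] == 0 ? matF : matM).push_back(i);
          if (matF.empty() || matM.empty()) {
            N = 0;
          } else {
            std::vector<int> newgeno((size_t)Nstar * G);
            std::vector<int> newsex(Nstar);
            for (int b = 0; b < Nstar; ++b) {
              int mo = matF[runif_int((int)matF.size())];
              int fa = matM[runif_int((int)matM.size())];
              for (int l = 0; l < L; ++l) {
                newgeno[(size_t)b * G + 2 * l] =
                  geno[(size_t)mo * G + 2 * l + runif_int(2)];
                newgeno[(size_t)b * G + 2 * l + 1] =
                  geno[(size_t)fa * G + 2 * l + runif_int(2)];
              }
              newsex[b] = (unif_rand() < 0.5) ? 0 : 1;
            }
            geno.swap(newgeno);
            sex.swap(newsex);
            N = Nstar;
            age.assign(N, mat_age);
            for (int l = 0; l < L; ++l) {
              std::fill(cnt[l].begin(), cnt[l].end(), 0);
              ndist[l] = 0;
            }
            for (int i = 0; i < N; ++i)
              for (int l = 0; l < L; ++l)
                for (int c = 0; c < 2; ++c) {
                  int a = geno[(size_t)i * G + 2 * l + c];
                  if (cnt[l][a]++ == 0) ndist[l]++;
                }
          }
        } else {
          // survival
          int i = 0;
          while (i < N) {
            if (++age[i] > lifespan) {
              for (int l = 0; l < L; ++l)
                for (int c = 0; c < 2; ++c) {
                  int a = geno[(size_t)i * G + 2 * l + c];
                  if (--cnt[l][a] == 0) ndist[l]--;
                }
              int last = N - 1;
              if (i != last) {
                age[i] = age[last];
                sex[i] = sex[last];
                for (int g = 0; g < G; ++g)
                  geno[(size_t)i * G + g] = geno[(size_t)last * G + g];
              }
              age.pop_back(); sex.pop_back();
              geno.resize((size_t)last * G);
              N = last;
            } else {
              ++i;
            }
          }
          // reproduction, female-limited recruitment; a year that requires
          // births but has no mature adult of either sex is a reproductive
          // failure and the population is recorded as extinct
          int births = Nstar - N;
          if (births > 0) {
            matF.clear(); matM.clear();
            for (int j = 0; j < N; ++j)
              if (age[j] >= mat_age)
                (sex[j] == 0 ? matF : matM).push_back(j);
            if (matF.empty() || matM.empty()) {
              births = 0;
              N = 0;
              age.clear(); sex.clear(); geno.clear();
              for (int l = 0; l < L; ++l) {
                std::fill(cnt[l].begin(), cnt[l].end(), 0);
                ndist[l] = 0;
              }
            } else if (fecundity > 0) {
              long cap = (long)fecundity * (long)matF.size();
              if (births > cap) births = (int)cap;
            }
            for (int b = 0; b < births; ++b) {
              int mo = matF[runif_int((int)matF.size())];
              int fa = matM[runif_int((int)matM.size())];
              size_t base = geno.size();
              geno.resize(base + G);
              for (int l = 0; l < L; ++l) {
                int am = geno[(size_t)mo * G + 2 * l + runif_int(2)];
                int af = geno[(size_t)fa * G + 2 * l + runif_int(2)];
                geno[base + 2 * l] = am;
                geno[base + 2 * l + 1] = af;
                if (cnt[l][am]++ == 0) ndist[l]++;
                if (cnt[l][af]++ == 0) ndist[l]++;
              }
              age.push_back(0);
              sex.push_back(unif_rand() < 0.5 ? 0 : 1);
              ++N;
            }
          }
        }
        if (N == 0 && ext == NA_INTEGER) ext = y;
      }
      census(y, it) = N;
      if (N == 0) {
        na_mat(y, it) = NA_REAL;
        het_mat(y, it) = NA_REAL;
      } else {
        double na = 0.0, het = 0.0;
        double tot = 2.0 * N;
        for (int l = 0; l < L; ++l) {
          na += ndist[l];
          double s2 = 0.0;
          for (int a = 0; a < ft.K[l]; ++a) {
            double p = cnt[l][a] / tot;
            s2 += p * p;
          }
          het += 1.0 - s2;
        }
        na_mat(y, it) = na / L;
        het_mat(y, it) = het / L;
      }
    }
    extinct_year[it] = ext;
    if (return_genotypes) {
      IntegerMatrix gm(N, G);
      for (int i = 0; i < N; ++i)
        for (int g = 0; g < G; ++g)
          gm(i, g) = geno[(size_t)i * G + g] + 1;  // 1-based allele codes
      terminal[it] = gm;
    }
  }
  return List::create(_["census"] = census, _["na"] = na_mat,
                      _["het"] = het_mat, _["extinct_year"] = extinct_year,
                      _["terminal"] = terminal);
}
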