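// Random-finite-set particle filter core.
//
// Particles are sets of distinct source-grid indices (0..maxDipoles of them);
// moments are not part of the state but are refit from the data at every
// sample by ridge least squares. All randomness flows through R's RNG
// (unif_rand) in a documented call order so runs are bit-reproducible from
// set.seed(): initialization (count, then locations per particle), then per
// sample: resampling (one uniform), evolution (per particle: death draws in
// storage order, then move draw + neighbor choice per survivor, then birth
// draw + location draw).

#include <RcppArmadillo.h>
#include <map>
#include <vector>

using namespace Rcpp;

static inline int unif_int(int n) {
    // uniform on 0..n-1
    int k = (int)(unif_rand() * n);
    return k >= n ? n - 1 : k;
}

// Ridge moment fit for one configuration. locs are 0-based point indices.
// Returns residual sum of squares and fills M (dof x k) with the moments.
static double fit_config(const arma::mat& G, const arma::vec& y, double yy,
                         const std::vector<int>& locs, int dof, double lambda,
                         arma::mat& M) {
    int k = (int)locs.size();
    if (k == 0) { M.set_size(0, 0); return yy; }
    int d = dof * k;
    arma::uvec cols(d);
    for (int i = 0; i < k; ++i)
        for (int j = 0; j < dof; ++j)
            cols[dof * i + j] = (arma::uword)(dof * locs[i] + j);
    arma::mat X = G.cols(cols);
    arma::mat A = X.t() * X;
    arma::vec b = X.t() * y;
    arma::mat Ar = A;
    Ar.diag() += lambda;
    arma::vec m;
    if (!arma::solve(m, Ar, b, arma::solve_opts::likely_sympd))
        m = arma::pinv(Ar) * b;
    double rss = yy - 2.0 * arma::dot(b, m) + arma::dot(m, A * m);
    if (rss < 0) rss = 0; // numerical guard
    M = arma::reshape(m, dof, k);
    return rss;
}

// [[Rcpp::export]]
List cpp_fit_moments(const arma::mat& G, const arma::vec& y,
                     const IntegerVector& locs, int dof, double lambda) {
    std::vector<int> l(locs.size());
    for (int i = 0; i < locs.size(); ++i) l[i] = locs[i] - 1;
    double yy = arma::dot(y, y);
    arma::mat M;
    double rss = fit_config(G, y, yy, l, dof, lambda, M);
    return List::create(_["moments"] = M, _["rss"] = rss);
}

// [[Rcpp::export]]
IntegerVector cpp_systematic_resample(const NumericVector& w) {
    int n = w.size();
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += w[i];
    if (!(tot > 0) || !R_finite(tot))
        stop("degenerate weights: cannot resample");
    IntegerVector out(n);
    double u = unif_rand() / n;
    double cum = 0.0;
    int j = 0;
    for (int i = 0; i < n; ++i) {
        cum += w[i] / tot;
        while (j < n && u < cum) {
            out[j] = i + 1;
            ++j;
            u += 1.0 / n;
        }
    }
    while (j < n) out[j++] = n; // guard against terminal rounding
    return out;
}

static std::vector<std::vector<int>> convert_neighbors(const List& nb) {
    int n = nb.size();
    std::vector<std::vector<int>> out(n);
    for (int i = 0; i < n; ++i) {
        IntegerVector v = nb[i];
        out[i].resize(v.size());
        for (int j = 0; j < v.size(); ++j) out[i][j] = v[j] - 1;
    }
    return out;
}

static bool contains(const std::vector<int>& v, int x, int skip = -1) {
    for (int i = 0; i < (int)v.size(); ++i)
        if (i != skip && v[i] == x) return true;
    return false;
}

// One evolution move applied in place; documented RNG call order.
static void evolve_one(std::vector<int>& locs,
                       const std::vector<std::vector<int>>& nb, int ngrid,
                       double pBirth, double pDeath, double pMove, int nmax) {
    // deaths, in storage order
    std::vector<int> surv;
    surv.reserve(locs.size());
    for (size_t i = 0; i < locs.size(); ++i)
        if (unif_rand() >= pDeath) surv.push_back(locs[i]);
    // moves: each survivor, in order, jumps to a uniformly chosen neighbor
    // (self included in the neighbor lists); collisions are rejected
    for (size_t i = 0; i < surv.size(); ++i) {
        if (unif_rand() < pMove) {
            const std::vector<int>& cand = nb[surv[i]];
            int tgt = cand[unif_int((int)cand.size())];
            if (!contains(surv, tgt, (int)i)) surv[i] = tgt;
        }
    }
    // birth at a uniform grid point, rejected on collision or when full
    if ((int)surv.size() < nmax && unif_rand() < pBirth) {
        int g = unif_int(ngrid);
        if (!contains(surv, g)) surv.push_back(g);
    }
    locs.swap(surv);
}

// [[Rcpp::export]]
List cpp_evolve(const List& particles, const List& neighbors, int ngrid,
                double pBirth, double pDeath, double pMove, int nmax) {
    std::vector<std::vector<int>> nb = convert_neighbors(neighbors);
    int np = particles.size();
    List out(np);
    for (int p = 0; p < np; ++p) {
        IntegerVector v = particles[p];
        std::vector<int> locs(v.size());
        for (int i = 0; i < v.size(); ++i) locs[i] = v[i] - 1;
        evolve_one(locs, nb, ngrid, pBirth, pDeath, pMove, nmax);
        IntegerVector o(locs.size());
        for (size_t i = 0; i < locs.size(); ++i) o[i] = locs[i] + 1;
        out[p] = o;
    }
    return out;
}

// [[Rcpp::export]]
List cpp_initialize_particles(int np, int nmax, int ngrid) {
    if (nmax > ngrid)
        stop("configuration error: maxDipoles exceeds the source-space size");
    List out(np);
    for (int p = 0; p < np; ++p) {
        int k = unif_int(nmax + 1);
        std::vector<int> locs;
        locs.reserve(k);
        while ((int)locs.size() < k) {
            int g = unif_int(ngrid);
            if (!contains(locs, g)) locs.push_back(g);
        }
        IntegerVector o(k);
        for (int i = 0; i < k; ++i) o[i] = locs[i] + 1;
        out[p] = o;
    }
    return out;
}

// Full filtering pass. Returns per-sample model-order posterior, its mode,
// a compact pooled-dipole table (grid index, weight mass, mean moment) over
// the particles carrying exactly nHat dipoles, optional particle snapshots,
// and the effective sample size.
// [[Rcpp::export]]
List cpp_run_filter(const arma::mat& G, const arma::mat& Y,
                    const List& neighbors, int dof, int np, int nmax,
                    double pBirth, double pDeath, double pMove,
                    double lambda, double noiseScale2, double resampleESS,
                    Nullable<List> init, IntegerVector snapshotAt,
                    bool verbose) {
    const int T = Y.n_cols;
    const int ngrid = (int)(G.n_cols / dof);
    std::vector<std::vector<int>> nb = convert_neighbors(neighbors);
    if ((int)nb.size() != ngrid)
        stop("neighbor list length does not match the lead-field size");

    // particle state
    std::vector<std::vector<int>> locs(np);
    if (init.isNotNull()) {
        List ini(init);
        if (ini.size() != np) stop("initial particle list must have length np");
        for (int p = 0; p < np; ++p) {
            IntegerVector v = ini[p];
            locs[p].resize(v.size());
            for (int i = 0; i < v.size(); ++i) locs[p][i] = v[i] - 1;
        }
    } else {
        for (int p = 0; p < np; ++p) {
            int k = unif_int(nmax + 1);
            while ((int)locs[p].size() < k) {
                int g = unif_int(ngrid);
                if (!contains(locs[p], g)) locs[p].push_back(g);
            }
        }
    }
    std::vector<double> logw_carry(np, 0.0); // log prior weights (uniform)

    arma::mat orderPost(T, nmax + 1, arma::fill::zeros);
    IntegerVector nHat(T);
    NumericVector essOut(T);
    List pooled(T);
    std::map<int, int> snapIdx;
    for (int i = 0; i < snapshotAt.size(); ++i)
        snapIdx[snapshotAt[i] - 1] = i;
    List snaps(snapshotAt.size());

    std::vector<double> logw(np), w(np);
    for (int t = 0; t < T; ++t) {
        arma::vec y = Y.col(t);
        double yy = arma::dot(y, y);

        // step 1: weighting (with per-sample caching of repeated configs)
        std::map<std::vector<int>, std::pair<double, arma::mat>> cache;
        std::vector<const arma::mat*> Mptr(np);
        for (int p = 0; p < np; ++p) {
            std::vector<int> key = locs[p];
            std::sort(key.begin(), key.end());
            auto it = cache.find(key);
            if (it == cache.end()) {
                arma::mat M;
                double rss = fit_config(G, y, yy, key, dof, lambda, M);
                it = cache.emplace(key,
                    std::make_pair(rss, std::move(M))).first;
            }
            logw[p] = logw_carry[p] - it->second.first / (2.0 * noiseScale2);
            Mptr[p] = &it->second.second;
            locs[p] = std::move(key); // canonical (sorted) storage
        }
        double mx = logw[0];
        for (int p = 1; p < np; ++p) if (logw[p] > mx) mx = logw[p];
        double tot = 0.0;
        for (int p = 0; p < np; ++p) { w[p] = std::exp(logw[p] - mx); tot += w[p]; }
        if (!(tot > 0) || !R_finite(tot))
            stop("degenerate weights at sample %d", t + 1);
        double ess = 0.0;
        for (int p = 0; p < np; ++p) { w[p] /= tot; ess += w[p] * w[p]; }
        ess = 1.0 / ess;
        essOut[t] = ess;

        // step 2: model-order posterior, mode, pooled conditional dipoles
        for (int p = 0; p < np; ++p)
            orderPost(t, (int)locs[p].size()) += w[p];
        int kmode = 0;
        for (int k = 1; k <= nmax; ++k)
            if (orderPost(t, k) > orderPost(t, kmode)) kmode = k;
        nHat[t] = kmode;
        std::map<int, std::vector<double>> acc; // index -> (w, w*moment...)
        if (kmode > 0) {
            for (int p = 0; p < np; ++p) {
                if ((int)locs[p].size() != kmode || w[p] == 0.0) continue;
                const arma::mat& M = *Mptr[p];
                for (int i = 0; i < kmode; ++i) {
                    std::vector<double>& a = acc[locs[p][i]];
                    if (a.empty()) a.assign(dof + 1, 0.0);
                    a[0] += w[p];
                    for (int j = 0; j < dof; ++j)
                        a[j + 1] += w[p] * M(j, i);
                }
            }
        }
        {
            NumericMatrix tab((int)acc.size(), dof + 2);
            int r = 0;
            for (auto& kv : acc) {
                tab(r, 0) = kv.first + 1;
                tab(r, 1) = kv.second[0];
                for (int j = 0; j < dof; ++j)
                    tab(r, j + 2) = kv.second[0] > 0 ?
                        kv.second[j + 1] / kv.second[0] : 0.0;
                ++r;
            }
            pooled[t] = tab;
        }

        auto si = snapIdx.find(t);
        if (si != snapIdx.end()) {
            List ps(np);
            NumericVector pw(np);
            for (int p = 0; p < np; ++p) {
                IntegerVector o((int)locs[p].size());
                for (size_t i = 0; i < locs[p].size(); ++i) o[i] = locs[p][i] + 1;
                ps[p] = o;
                pw[p] = w[p];
            }
            snaps[si->second] = List::create(_["particles"] = ps,
                _["weights"] = pw, _["sample"] = t + 1);
        }

        // step 3: resampling (systematic), by default at every sample
        if (resampleESS >= 1.0 || ess < resampleESS * np) {
            NumericVector wv(w.begin(), w.end());
            IntegerVector idx = cpp_systematic_resample(wv);
            std::vector<std::vector<int>> nl(np);
            for (int p = 0; p < np; ++p) nl[p] = locs[idx[p] - 1];
            locs.swap(nl);
            std::fill(logw_carry.begin(), logw_carry.end(), 0.0);
        } else {
            for (int p = 0; p < np; ++p) logw_carry[p] = std::log(w[p]);
        }

        // step 4: random evolution with birth/death/jumps
        for (int p = 0; p < np; ++p)
            evolve_one(locs[p], nb, ngrid, pBirth, pDeath, pMove, nmax);

        if (verbose && ((t + 1) % 50 == 0 || t + 1 == T))
            Rcout << "  sample " << (t + 1) << "/" << T
                  << "  ESS " << (int)ess << "  nHat " << kmode << "\n";
        if ((t & 31) == 0) checkUserInterrupt();
    }

    return List::create(_["orderPosterior"] = orderPost, _["nHat"] = nHat,
        _["pooled"] = pooled, _["snapshots"] = snaps, _["ess"] = essOut);
}
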