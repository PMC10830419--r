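#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Gamete formation under the Haldane model: crossover count per chromosome is
// Poisson(map length in Morgans), breakpoints uniform, no interference.
// Haplotypes are 0/1 vectors over the informative-site grid (1 = malinche).
static void make_gamete(const IntegerVector& chrStart,
                        const NumericVector& gpos,
                        const NumericVector& morgans,
                        const int* hapA, const int* hapB,
                        int* out) {
    const int nChr = morgans.size();
    std::vector<double> bp;
    for (int c = 0; c < nChr; ++c) {
        const int s0 = chrStart[c], s1 = chrStart[c + 1];
        const double L = morgans[c];
        const int k = (int) R::rpois(L);
        int phase = (unif_rand() < 0.5) ? 0 : 1;
        if (k == 0) {
            const int* h = phase ? hapB : hapA;
            for (int i = s0; i < s1; ++i) out[i] = h[i];
        } else {
            bp.resize(k);
            for (int j = 0; j < k; ++j) bp[j] = unif_rand() * L;
            std::sort(bp.begin(), bp.end());
            int j = 0;
            for (int i = s0; i < s1; ++i) {
                while (j < k && bp[j] < gpos[i]) { ++j; phase ^= 1; }
                out[i] = phase ? hapB[i] : hapA[i];
            }
        }
    }
}

// Multiplicative zygote viability. Fitness of the penalized homozygote is
// 1 - s, of the heterozygote 1 - h*s, applied only when the zygote's
// mitochondrial haplotype matches the locus's mitochondrial partner. An
// optional pairwise epistatic term multiplies in (1 - e) when locus A is
// penalized-homozygous and locus B carries at least one penalized allele.
static double zygote_fitness(const int* hm, const int* hp, int mito,
                             const IntegerVector& lociSite,
                             const NumericVector& lociS,
                             const NumericVector& lociH,
                             const IntegerVector& lociMito,
                             const IntegerVector& lociPenHom,
                             int epiA, int epiB, int epiMito, double epiE) {
    double w = 1.0;
    const int nl = lociSite.size();
    for (int l = 0; l < nl; ++l) {
        if (mito != lociMito[l]) continue;
        const int site = lociSite[l];
        const int call = hm[site] + hp[site];
        if (call == lociPenHom[l]) w *= 1.0 - lociS[l];
        else if (call == 1) w *= 1.0 - lociH[l] * lociS[l];
    }
    if (epiA >= 0 && mito == epiMito) {
        const int callA = hm[lociSite[epiA]] + hp[lociSite[epiA]];
        if (callA == lociPenHom[epiA]) {
            const int callB = hm[lociSite[epiB]] + hp[lociSite[epiB]];
            const int penB = (lociPenHom[epiB] == 0) ? 2 - callB : callB;
            if (penB >= 1) w *= 1.0 - epiE;
        }
    }
    return w;
}

// [[Rcpp::export(name = ".cpp_simulate_gametes")]]
IntegerMatrix cpp_simulate_gametes(IntegerVector chrStart, NumericVector gpos,
                                   NumericVector morgans, int n) {
    const int nSites = gpos.size();
    std::vector<int> ones(nSites, 1), zeros(nSites, 0);
    IntegerMatrix out(nSites, n);
    std::vector<int> g(nSites);
    for (int i = 0; i < n; ++i) {
        make_gamete(chrStart, gpos, morgans, ones.data(), zeros.data(), g.data());
        for (int s = 0; s < nSites; ++s) out(s, i) = g[s];
    }
    return out;
}

// F1 intercross: both parents heterozygous genome-wide (one malinche, one
// birchmanni haplotype); all offspring carry the malinche mitochondria.
// [[Rcpp::export(name = ".cpp_simulate_cross")]]
List cpp_simulate_cross(IntegerVector chrStart, NumericVector gpos,
                        NumericVector morgans, int n,
                        IntegerVector lociSite, NumericVector lociS,
                        NumericVector lociH, IntegerVector lociMito,
                        IntegerVector lociPenHom,
                        int epiA, int epiB, int epiMito, double epiE,
                        bool resample, double maxTries) {
    const int nSites = gpos.size();
    std::vector<int> ones(nSites, 1), zeros(nSites, 0);
    std::vector<int> gm(nSites), gp(nSites);
    const int mito = 1; // maternal, malinche
    IntegerMatrix calls(nSites, n);
    int kept = 0;
    double tries = 0;
    // resample: redraw zygotes until n survivors; otherwise draw exactly n
    // zygotes and return the realized survivor count.
    while (resample ? (kept < n) : (tries < n)) {
        if (resample && tries >= maxTries)
            stop("exceeded %.0f zygote draws without reaching %d survivors; selection too strong?",
                 maxTries, n);
        ++tries;
        make_gamete(chrStart, gpos, morgans, ones.data(), zeros.data(), gm.data());
        make_gamete(chrStart, gpos, morgans, ones.data(), zeros.data(), gp.data());
        const double w = zygote_fitness(gm.data(), gp.data(), mito, lociSite, lociS,
                                        lociH, lociMito, lociPenHom,
                                        epiA, epiB, epiMito, epiE);
        if (w >= 1.0 || unif_rand() < w) {
            for (int s = 0; s < nSites; ++s) calls(s, kept) = gm[s] + gp[s];
            ++kept;
        }
    }
    if (kept < n) {
        IntegerMatrix trimmed(nSites, kept);
        for (int i = 0; i < kept; ++i)
            for (int s = 0; s < nSites; ++s) trimmed(s, i) = calls(s, i);
        calls = trimmed;
    }
    return List::create(_["calls"] = calls, _["survivors"] = kept,
                        _["zygotes"] = tries);
}

// Wright-Fisher hybrid swarm with maternal mitochondrial transmission and the
// same gamete/viability machinery; survivors enter the next generation by
// rejection sampling of proposed zygotes.
// [[Rcpp::export(name = ".cpp_simulate_swarm")]]
List cpp_simulate_swarm(IntegerVector chrStart, NumericVector gpos,
                        NumericVector morgans,
                        IntegerVector founderSpecies, IntegerVector founderMito,
                        int generations,
                        IntegerVector lociSite, NumericVector lociS,
                        NumericVector lociH, IntegerVector lociMito,
                        IntegerVector lociPenHom,
                        int epiA, int epiB, int epiMito, double epiE,
                        double migration, double migMalinche,
                        double maxTriesPerIndiv) {
    const int nSites = gpos.size();
    const int N = founderSpecies.size();
    std::vector<int> h1(static_cast<size_t>(nSites) * N), h2(h1.size());
    std::vector<int> n1(h1.size()), n2(h1.size());
    std::vector<int> mito(founderMito.begin(), founderMito.end());
    std::vector<int> nmito(N);
    for (int i = 0; i < N; ++i) {
        const int v = founderSpecies[i];
        std::fill(h1.begin() + (size_t) i * nSites, h1.begin() + (size_t)(i + 1) * nSites, v);
        std::fill(h2.begin() + (size_t) i * nSites, h2.begin() + (size_t)(i + 1) * nSites, v);
    }
    const bool neutral = (lociSite.size() == 0 && epiA < 0);
    for (int g = 1; g <= generations; ++g) {
        double tries = 0;
        const double cap = maxTriesPerIndiv * N;
        for (int i = 0; i < N; ++i) {
            int* cm = n1.data() + (size_t) i * nSites;
            int* cp = n2.data() + (size_t) i * nSites;
            // island-model migration: a slot is filled by a pure parental
            // migrant carrying its own species' mitochondria
            if (migration > 0 && unif_rand() < migration) {
                const int sp = (unif_rand() < migMalinche) ? 1 : 0;
                std::fill(cm, cm + nSites, sp);
                std::fill(cp, cp + nSites, sp);
                nmito[i] = sp;
                continue;
            }
            for (;;) {
                if (++tries > cap)
                    stop("population extinct under selection at generation %d", g);
                int mom = (int)(unif_rand() * N); if (mom == N) mom = N - 1;
                int dad = mom;
                while (N > 1 && dad == mom) {
                    dad = (int)(unif_rand() * N); if (dad == N) dad = N - 1;
                }
                make_gamete(chrStart, gpos, morgans,
                            h1.data() + (size_t) mom * nSites,
                            h2.data() + (size_t) mom * nSites, cm);
                make_gamete(chrStart, gpos, morgans,
                            h1.data() + (size_t) dad * nSites,
                            h2.data() + (size_t) dad * nSites, cp);
                nmito[i] = mito[mom];
                if (neutral) break;
                const double w = zygote_fitness(cm, cp, nmito[i], lociSite, lociS,
                                                lociH, lociMito, lociPenHom,
                                                epiA, epiB, epiMito, epiE);
                if (w >= 1.0 || unif_rand() < w) break;
            }
        }
        h1.swap(n1); h2.swap(n2); mito.swap(nmito);
    }
    IntegerMatrix calls(nSites, N);
    IntegerVector mitoOut(N);
    for (int i = 0; i < N; ++i) {
        const int* a = h1.data() + (size_t) i * nSites;
        const int* b = h2.data() + (size_t) i * nSites;
        for (int s = 0; s < nSites; ++s) calls(s, i) = a[s] + b[s];
        mitoOut[i] = mito[i];
    }
    return List::create(_["calls"] = calls, _["mito"] = mitoOut);
}
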