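#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Symbol codes: A=0, C=1, G=2, T=3, ambiguous=4.
// Word codes: big-endian base-4 over k symbols (first base most significant).

static inline int rc_word(int w, int k) {
    // reverse complement of a word code: read digits LSB-first (= word
    // reversed), complement each (3 - b), emit MSB-first.
    int r = 0;
    for (int j = 0; j < k; ++j) {
        r = r * 4 + (3 - (w & 3));
        w >>= 2;
    }
    return r;
}

// [[Rcpp::export(name = ".pair_count_core")]]
IntegerVector pair_count_core(IntegerVector codes, int k, int dmax) {
    const int L = codes.size();
    const int nd = dmax - k + 1;
    IntegerVector m(nd);
    if (nd <= 0 || L < 2 * k) return m;

    const int nwords = 1 << (2 * k);
    // word validity, word code and run id per start position
    std::vector<int> wc(L, -1), rid(L, -1);
    int cur = -1; bool inrun = false;
    int w = 0, span = 0;
    const int mask = nwords - 1;
    for (int i = 0; i < L; ++i) {
        const int c = codes[i];
        if (c < 4) {
            if (!inrun) { cur++; inrun = true; span = 0; w = 0; }
            w = ((w << 2) | c) & mask;
            span++;
            if (span >= k) { wc[i - k + 1] = w; rid[i - k + 1] = cur; }
        } else {
            inrun = false;
        }
    }

    // bucket word-start positions by word code (counting sort keeps each
    // bucket position-sorted)
    std::vector<int> cnt(nwords + 1, 0);
    int nvalid = 0;
    for (int i = 0; i < L; ++i) if (wc[i] >= 0) { cnt[wc[i] + 1]++; nvalid++; }
    for (int t = 0; t < nwords; ++t) cnt[t + 1] += cnt[t];
    std::vector<int> pos(nvalid);
    {
        std::vector<int> wp(cnt.begin(), cnt.end() - 1);
        for (int i = 0; i < L; ++i) if (wc[i] >= 0) pos[wp[wc[i]]++] = i;
    }

    // for every word, sweep its positions against the reverse-complement
    // bucket with a two-pointer window [a+k, a+dmax]
    for (int t = 0; t < nwords; ++t) {
        const int a0 = cnt[t], a1 = cnt[t + 1];
        if (a0 == a1) continue;
        const int r = rc_word(t, k);
        const int b1 = cnt[r + 1];
        int j0 = cnt[r];
        if (j0 == b1) continue;
        for (int ai = a0; ai < a1; ++ai) {
            const int a = pos[ai];
            while (j0 < b1 && pos[j0] < a + k) j0++;
            for (int j = j0; j < b1 && pos[j] <= a + dmax; ++j) {
                if (rid[pos[j]] == rid[a]) m[pos[j] - a - k]++;
            }
        }
    }
    return m;
}

// [[Rcpp::export(name = ".simulate_runs_core")]]
IntegerVector simulate_runs_core(IntegerVector run_lengths, int k,
                                 NumericVector pi_cum, NumericMatrix trans_cum) {
    // Draws each run independently: an initial k-word from pi (truncated for
    // runs shorter than k), then one base at a time from the transition rows.
    // Uses R's RNG so results follow set.seed().
    const int nwords = pi_cum.size();
    long total = 0;
    for (int i = 0; i < run_lengths.size(); ++i) total += run_lengths[i];
    IntegerVector out(total);
    long o = 0;
    for (int ri = 0; ri < run_lengths.size(); ++ri) {
        const int Lr = run_lengths[ri];
        if (Lr <= 0) continue;
        // initial word ~ pi (binary search on the cumulative distribution)
        double u = unif_rand();
        int lo = 0, hi = nwords - 1;
        while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (pi_cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        int w = lo;
        const int take = Lr < k ? Lr : k;
        // emit the first `take` symbols of word w (big-endian digits)
        for (int j = 0; j < take; ++j) {
            out[o + j] = (w >> (2 * (k - 1 - j))) & 3;
        }
        const int mask = (nwords - 1) >> 2; // keep low k-1 digits
        for (int j = k; j < Lr; ++j) {
            double v = unif_rand();
            int b = 0;
            while (b < 3 && trans_cum(w, b) < v) b++;
            out[o + j] = b;
            w = ((w & mask) << 2) | b;
        }
        o += Lr;
    }
    return out;
}
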