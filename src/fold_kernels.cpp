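#include <Rcpp.h>
using namespace Rcpp;

// Per-row mean and sample variance over a column subset, computed in one
// strided pass without materialising the submatrix.  cols are 1-based.
// [[Rcpp::export]]
NumericMatrix row_moments_subset(NumericMatrix x, IntegerVector cols) {
    const int m = x.nrow(), n = cols.size();
    NumericMatrix out(m, 2);
    for (int ci = 0; ci < n; ++ci) {
        const double* col = &x(0, cols[ci] - 1);
        for (int r = 0; r < m; ++r) {
            out(r, 0) += col[r];
            out(r, 1) += col[r] * col[r];
        }
    }
    for (int r = 0; r < m; ++r) {
        const double mean = out(r, 0) / n;
        double v = (out(r, 1) - n * mean * mean) / (n - 1);
        out(r, 0) = mean;
        out(r, 1) = v > 0 ? v : 0.0;  // numerical guard
    }
    return out;
}

// Average ranks of selected rows over a column subset, straight from the
// full matrix (no intermediate subset copy).  rows/cols are 1-based.
// Small-range integer rows (streamline counts) use counting sort.
// [[Rcpp::export]]
NumericMatrix row_ranks_subset(NumericMatrix x, IntegerVector rows,
                               IntegerVector cols) {
    const int m = rows.size(), n = cols.size();
    NumericMatrix out(m, n);
    std::vector<double> row(n);
    std::vector<std::pair<double, int> > v(n);
    std::vector<int> cnt;
    std::vector<double> avgr;
    for (int ri = 0; ri < m; ++ri) {
        const int r = rows[ri] - 1;
        double mn = x(r, cols[0] - 1), mx = mn;
        bool isInt = true;
        for (int i = 0; i < n; ++i) {
            const double val = x(r, cols[i] - 1);
            row[i] = val;
            if (val < mn) mn = val;
            if (val > mx) mx = val;
            if (isInt && val != (double)(long long)val) isInt = false;
        }
        const double span = mx - mn;
        if (isInt && span <= 16.0 * n) {
            const int K = (int)span + 1;
            cnt.assign(K, 0);
            avgr.resize(K);
            for (int i = 0; i < n; ++i) ++cnt[(int)(row[i] - mn)];
            int cum = 0;
            for (int k = 0; k < K; ++k) {
                avgr[k] = cum + (cnt[k] + 1) / 2.0;
                cum += cnt[k];
            }
            for (int i = 0; i < n; ++i)
                out(ri, i) = avgr[(int)(row[i] - mn)];
        } else {
            for (int i = 0; i < n; ++i) v[i] = std::make_pair(row[i], i);
            std::sort(v.begin(), v.end());
            int i = 0;
            while (i < n) {
                int j = i;
                while (j + 1 < n && v[j + 1].first == v[i].first) ++j;
                const double avg = (i + j) / 2.0 + 1.0;
                for (int k = i; k <= j; ++k) out(ri, v[k].second) = avg;
                i = j + 1;
            }
        }
    }
    return out;
}

// Column sums of a row subset over a column subset (network strength of an
// edge set for a set of subjects).  rows/cols 1-based.
// [[Rcpp::export]]
NumericVector col_sums_subset(NumericMatrix x, IntegerVector rows,
                              IntegerVector cols) {
    const int m = rows.size(), n = cols.size();
    NumericVector out(n);
    for (int ci = 0; ci < n; ++ci) {
        const double* col = &x(0, cols[ci] - 1);
        double s = 0;
        for (int ri = 0; ri < m; ++ri) s += col[rows[ri] - 1];
        out[ci] = s;
    }
    return out;
}
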