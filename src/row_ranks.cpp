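#include <Rcpp.h>
using namespace Rcpp;

//' Row-wise average ranks
//'
//' Ranks each row of a numeric matrix with average ranks for ties, the
//' transform applied per edge before computing rank-based correlations.
//' Hot loop of every cross-validation fold, hence compiled.  Rows of
//' small-range integers (the streamline-count case) are ranked by counting
//' sort; anything else falls back to a comparison sort.
//'
//' @param x numeric matrix (edges in rows, subjects in columns)
//' @return matrix of the same shape holding within-row ranks
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix row_ranks(NumericMatrix x) {
    const int m = x.nrow(), n = x.ncol();
    NumericMatrix out(m, n);
    std::vector<double> row(n);
    std::vector<std::pair<double, int> > v(n);
    std::vector<int> cnt;
    std::vector<double> avgr;
    for (int r = 0; r < m; ++r) {
        double mn = x(r, 0), mx = mn;
        bool isInt = true;
        for (int i = 0; i < n; ++i) {
            const double val = x(r, i);
            row[i] = val;
            if (val < mn) mn = val;
            if (val > mx) mx = val;
            if (isInt && val != (double)(long long)val) isInt = false;
        }
        const double span = mx - mn;
        if (isInt && span <= 16.0 * n) {
            // counting ranks: tied group of size c starting after cum
            // smaller values gets average rank cum + (c + 1) / 2
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
                out(r, i) = avgr[(int)(row[i] - mn)];
        } else {
            for (int i = 0; i < n; ++i) v[i] = std::make_pair(row[i], i);
            std::sort(v.begin(), v.end());
            int i = 0;
            while (i < n) {
                int j = i;
                while (j + 1 < n && v[j + 1].first == v[i].first) ++j;
                const double avg = (i + j) / 2.0 + 1.0;  // 1-based
                for (int k = i; k <= j; ++k) out(r, v[k].second) = avg;
                i = j + 1;
            }
        }
    }
    return out;
}
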