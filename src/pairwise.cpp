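#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Fraction of the circumference of a circle of radius r centred at (px, py)
// that lies inside the rectangle [0, wx] x [0, wy] (Goreaud & Pelissier
// construction for rectangular windows). Requires 0 <= px <= wx etc.
static double circle_fraction_inside(double px, double py,
                                     double wx, double wy, double r) {
    if (r <= 0.0) return 1.0;
    double d[4] = {px, wx - px, py, wy - py}; // left, right, bottom, top
    double ext = 0.0;
    for (int i = 0; i < 4; ++i)
        if (d[i] < r) ext += 2.0 * std::acos(d[i] / r);
    // adjacent edge pairs share a corner: (left,bottom) (left,top)
    // (right,bottom) (right,top)
    int corners[4][2] = {{0, 2}, {0, 3}, {1, 2}, {1, 3}};
    for (int c = 0; c < 4; ++c) {
        double di = d[corners[c][0]], dj = d[corners[c][1]];
        if (di * di + dj * dj < r * r)
            ext -= (std::acos(di / r) + std::acos(dj / r) - M_PI / 2.0);
    }
    double frac = 1.0 - ext / (2.0 * M_PI);
    if (frac < 1e-6) frac = 1e-6; // numerical guard; unreachable for r < min(wx,wy)/2
    return frac;
}

// [[Rcpp::export]]
double cpp_circle_fraction_inside(double px, double py,
                                  double wx, double wy, double r) {
    return circle_fraction_inside(px, py, wx, wy, r);
}

// Weighted cumulative pair counts for the Ripley K estimator.
// Coordinates are assumed shifted so the window is [0,wx] x [0,wy].
// correction: 0 = none, 1 = toroidal, 2 = isotropic (Ripley weight).
// Returns sum over ordered pairs (i, j != i) of w_ij * 1[d_ij <= r_k].
// [[Rcpp::export]]
NumericVector cpp_ripley_pair_sums(NumericVector x, NumericVector y,
                                   double wx, double wy,
                                   NumericVector radii, int correction) {
    int n = x.size(), nr = radii.size();
    NumericVector out(nr);
    double rmax = radii[nr - 1];
    for (int i = 0; i < n; ++i) {
        for (int j = 0; j < n; ++j) {
            if (i == j) continue;
            double dx = std::fabs(x[i] - x[j]);
            double dy = std::fabs(y[i] - y[j]);
            if (correction == 1) {
                if (dx > wx / 2.0) dx = wx - dx;
                if (dy > wy / 2.0) dy = wy - dy;
            }
            if (dx > rmax || dy > rmax) continue;
            double d = std::sqrt(dx * dx + dy * dy);
            if (d > rmax) continue;
            double w = 1.0;
            if (correction == 2)
                w = 1.0 / circle_fraction_inside(x[i], y[i], wx, wy, d);
            int lo = std::lower_bound(radii.begin(), radii.end(), d) -
                     radii.begin();
            for (int k = lo; k < nr; ++k) out[k] += w;
        }
    }
    return out;
}

// For each point of (xq, yq), Euclidean distance to the nearest point of
// (xt, yt). exclude_self = true skips pairs with identical index (patterns
// must then be the same length and refer to the same points).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector xq, NumericVector yq,
                          NumericVector xt, NumericVector yt,
                          bool exclude_self) {
    int nq = xq.size(), nt = xt.size();
    NumericVector out(nq);
    for (int i = 0; i < nq; ++i) {
        double best = R_PosInf;
        for (int j = 0; j < nt; ++j) {
            if (exclude_self && i == j) continue;
            double dx = xq[i] - xt[j], dy = yq[i] - yt[j];
            double d2 = dx * dx + dy * dy;
            if (d2 < best) best = d2;
        }
        out[i] = std::sqrt(best);
    }
    return out;
}

// Cumulative neighbour counts: for each query point, number of target points
// within each radius (radii ascending). exclude_self as above;
// exclude_coincident drops zero-distance targets (a molecule's own record
// appearing in the other channel).
// [[Rcpp::export]]
IntegerMatrix cpp_count_in_radii(NumericVector xq, NumericVector yq,
                                 NumericVector xt, NumericVector yt,
                                 NumericVector radii, bool exclude_self,
                                 bool exclude_coincident = false) {
    int nq = xq.size(), nt = xt.size(), nr = radii.size();
    IntegerMatrix out(nq, nr);
    double rmax = radii[nr - 1];
    for (int i = 0; i < nq; ++i) {
        for (int j = 0; j < nt; ++j) {
            if (exclude_self && i == j) continue;
            if (exclude_coincident && xq[i] == xt[j] && yq[i] == yt[j])
                continue;
            double dx = std::fabs(xq[i] - xt[j]);
            if (dx > rmax) continue;
            double dy = std::fabs(yq[i] - yt[j]);
            if (dy > rmax) continue;
            double d = std::sqrt(dx * dx + dy * dy);
            if (d > rmax) continue;
            int lo = std::lower_bound(radii.begin(), radii.end(), d) -
                     radii.begin();
            for (int k = lo; k < nr; ++k) out(i, k) += 1;
        }
    }
    return out;
}

// Classic DBSCAN on 2-D points. min_neighbors counts OTHER points within eps
// (the point itself is excluded). Labels: 0 = noise, clusters numbered from 1
// in order of discovery (input order), so border-point ties resolve to the
// first-discovered cluster.
// [[Rcpp::export]]
IntegerVector cpp_dbscan(NumericVector x, NumericVector y,
                         double eps, int min_neighbors) {
    int n = x.size();
    IntegerVector labels(n, 0);
    if (n == 0) return labels;
    double eps2 = eps * eps;

    std::vector<std::vector<int>> nbrs(n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double dx = x[i] - x[j], dy = y[i] - y[j];
            if (dx * dx + dy * dy <= eps2) {
                nbrs[i].push_back(j);
                nbrs[j].push_back(i);
            }
        }
    }
    std::vector<bool> core(n);
    for (int i = 0; i < n; ++i)
        core[i] = (int)nbrs[i].size() >= min_neighbors;

    int cl = 0;
    std::vector<int> stack;
    for (int i = 0; i < n; ++i) {
        if (labels[i] != 0 || !core[i]) continue;
        ++cl;
        labels[i] = cl;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
            int p = stack.back();
            stack.pop_back();
            for (size_t k = 0; k < nbrs[p].size(); ++k) {
                int q = nbrs[p][k];
                if (labels[q] != 0) continue;
                labels[q] = cl;
                if (core[q]) stack.push_back(q);
            }
        }
    }
    return labels;
}
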