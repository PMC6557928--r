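#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Compact per-reaction law encoding assembled on the R side:
//   kind: 0 = Michaelis-Menten (product of saturations), 1 = mass action
//   p1:   vmax or k (forward)
//   idx:  0-based driving-species indices
//   p2:   km or kinetic-order values, aligned with idx
//   rp1:  vmaxr or kr (0 = irreversible law)
//   ridx, rp2: reverse part
//   rev:  reaction-level reversible flag (negative net flux allowed)

static double eval_one(double kind, double p1, const int* idx, const double* p2,
                       int n, double rp1, const int* ridx, const double* rp2,
                       int rn, bool rev, const double* x) {
    double v;
    if (kind == 0.0) {
        v = p1;
        for (int i = 0; i < n; ++i) {
            double s = x[idx[i]];
            if (s < 0) s = 0;
            v *= s / (p2[i] + s);
        }
        if (rp1 > 0) {
            double vr = rp1;
            for (int i = 0; i < rn; ++i) {
                double s = x[ridx[i]];
                if (s < 0) s = 0;
                vr *= s / (rp2[i] + s);
            }
            v -= vr;
        }
    } else {
        v = p1;
        for (int i = 0; i < n; ++i) {
            double s = x[idx[i]];
            if (s < 0) s = 0;
            if (s == 0.0 && p2[i] > 0) { v = 0; break; }
            if (p2[i] != 0.0) v *= std::pow(s, p2[i]);
        }
        if (rp1 > 0) {
            double vr = rp1;
            for (int i = 0; i < rn; ++i) {
                double s = x[ridx[i]];
                if (s < 0) s = 0;
                if (s == 0.0 && rp2[i] > 0) { vr = 0; break; }
                if (rp2[i] != 0.0) vr *= std::pow(s, rp2[i]);
            }
            v -= vr;
        }
    }
    if (!rev && v < 0) v = 0;
    return v;
}

struct LawSet {
    int nr;
    std::vector<double> kind, p1, rp1;
    std::vector<bool> rev;
    std::vector< std::vector<int> > idx, ridx;
    std::vector< std::vector<double> > p2, rp2;
    explicit LawSet(List laws) {
        nr = laws.size();
        kind.resize(nr); p1.resize(nr); rp1.resize(nr); rev.resize(nr);
        idx.resize(nr); ridx.resize(nr); p2.resize(nr); rp2.resize(nr);
        for (int j = 0; j < nr; ++j) {
            List l = laws[j];
            kind[j] = as<double>(l["kind"]);
            p1[j] = as<double>(l["p1"]);
            rp1[j] = as<double>(l["rp1"]);
            rev[j] = as<bool>(l["rev"]);
            idx[j] = as< std::vector<int> >(l["idx"]);
            p2[j] = as< std::vector<double> >(l["p2"]);
            ridx[j] = as< std::vector<int> >(l["ridx"]);
            rp2[j] = as< std::vector<double> >(l["rp2"]);
        }
    }
    double rate(int j, const double* x, double activity) const {
        return activity * eval_one(kind[j], p1[j],
                                   idx[j].data(), p2[j].data(), (int)idx[j].size(),
                                   rp1[j], ridx[j].data(), rp2[j].data(),
                                   (int)ridx[j].size(), rev[j], x);
    }
};

// [[Rcpp::export]]
NumericVector rate_eval(NumericVector state, List laws, NumericVector activity) {
    LawSet L(laws);
    NumericVector v(L.nr);
    for (int j = 0; j < L.nr; ++j)
        v[j] = L.rate(j, state.begin(), activity[j]);
    return v;
}

// ---- indexed binary min-heap over putative firing times -------------------
// Ties broken by reaction index (lowest fires first) for reproducibility.
struct Heap {
    std::vector<double> key;
    std::vector<int> heap, pos;  // heap: idx at node; pos: node of idx
    int n;
    explicit Heap(const std::vector<double>& keys) : key(keys) {
        n = key.size();
        heap.resize(n); pos.resize(n);
        for (int i = 0; i < n; ++i) { heap[i] = i; pos[i] = i; }
        for (int i = n / 2 - 1; i >= 0; --i) down(i);
    }
    bool less(int a, int b) const {  // compare reaction ids a, b
        if (key[a] != key[b]) return key[a] < key[b];
        return a < b;
    }
    void swapN(int i, int j) {
        std::swap(heap[i], heap[j]);
        pos[heap[i]] = i; pos[heap[j]] = j;
    }
    void up(int i) {
        while (i > 0) {
            int p = (i - 1) / 2;
            if (less(heap[i], heap[p])) { swapN(i, p); i = p; } else break;
        }
    }
    void down(int i) {
        for (;;) {
            int l = 2 * i + 1, r = l + 1, m = i;
            if (l < n && less(heap[l], heap[m])) m = l;
            if (r < n && less(heap[r], heap[m])) m = r;
            if (m == i) break;
            swapN(i, m); i = m;
        }
    }
    void update(int id, double newkey) {
        double old = key[id];
        key[id] = newkey;
        if (newkey < old) up(pos[id]); else down(pos[id]);
    }
    int top() const { return heap[0]; }
    double topkey() const { return key[heap[0]]; }
};

// Gibson-Bruck next-reaction method. State in integer copy numbers;
// propensities are the macroscopic laws evaluated at n/omega, scaled by
// omega. Boundary species are never updated (their copy number is the clamp).
// Returns copies sampled on tgrid plus the event count.
// [[Rcpp::export]]
List nrm_run(NumericVector init_copies, List laws,
             List stoich_idx, List stoich_delta, List depgraph,
             NumericVector tgrid, double omega, double max_events) {
    int ns = init_copies.size();
    LawSet L(laws);
    int nr = L.nr;
    int nt = tgrid.size();

    std::vector< std::vector<int> > sidx(nr), sdel(nr), deps(nr);
    for (int j = 0; j < nr; ++j) {
        sidx[j] = as< std::vector<int> >(stoich_idx[j]);
        sdel[j] = as< std::vector<int> >(stoich_delta[j]);
        deps[j] = as< std::vector<int> >(depgraph[j]);
    }

    std::vector<double> n(ns), conc(ns);
    for (int i = 0; i < ns; ++i) n[i] = init_copies[i];
    auto refresh_conc = [&]() { for (int i = 0; i < ns; ++i) conc[i] = n[i] / omega; };
    refresh_conc();

    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> a(nr), tau(nr);
    RNGScope scope;
    for (int j = 0; j < nr; ++j) {
        a[j] = omega * L.rate(j, conc.data(), 1.0);
        if (a[j] < 0) a[j] = 0;
        tau[j] = a[j] > 0 ? R::exp_rand() / a[j] : INF;
    }
    Heap H(tau);

    NumericMatrix out(nt, ns);
    int g = 0;
    double t = 0;
    double events = 0;
    auto record_until = [&](double tnext) {
        while (g < nt && tgrid[g] <= tnext) {
            for (int i = 0; i < ns; ++i) out(g, i) = n[i] / omega;
            ++g;
        }
    };

    for (;;) {
        int mu = H.top();
        double tmu = H.topkey();
        if (!std::isfinite(tmu) || tmu > tgrid[nt - 1]) {
            record_until(tgrid[nt - 1]);
            break;
        }
        record_until(std::nextafter(tmu, 0.0));
        t = tmu;
        // fire mu
        for (size_t q = 0; q < sidx[mu].size(); ++q) {
            n[sidx[mu][q]] += sdel[mu][q];
            if (n[sidx[mu][q]] < 0) n[sidx[mu][q]] = 0;  // guard
        }
        refresh_conc();
        if (++events >= max_events)
            stop("stochastic simulation exceeded the event budget (%.0f)", max_events);
        for (size_t q = 0; q < deps[mu].size(); ++q) {
            int al = deps[mu][q];
            double anew = omega * L.rate(al, conc.data(), 1.0);
            if (anew < 0) anew = 0;
            double tnew;
            if (al == mu) {
                tnew = anew > 0 ? t + R::exp_rand() / anew : INF;
            } else if (anew == 0) {
                tnew = INF;
            } else if (a[al] > 0 && std::isfinite(tau[al])) {
                tnew = t + (a[al] / anew) * (tau[al] - t);
            } else {
                tnew = t + R::exp_rand() / anew;
            }
            a[al] = anew;
            tau[al] = tnew;
            H.update(al, tnew);
        }
    }
    return List::create(_["copies"] = out, _["events"] = events);
}
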