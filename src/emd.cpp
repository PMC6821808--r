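#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact solver for the balanced transportation problem
//   min sum_ij c_ij * x_ij  s.t.  sum_j x_ij = p_i, sum_i x_ij = q_j, x >= 0
// by the transportation simplex (MODI / u-v method): north-west corner
// initial basis, dual computation on the basis tree, Dantzig entering rule
// with deterministic tie-breaking, cycle pivot. The basis always holds
// exactly n+m-1 cells (degenerate zero-mass cells included), forming a
// spanning tree of the bipartite row/column vertex set; all per-iteration
// scratch is preallocated and the tree adjacency is rebuilt in O(n+m) by
// counting sort.

struct BasisCell {
    int i, j;
    double x;
};

// [[Rcpp::export(name = ".emd_lp_cpp")]]
List emd_lp_cpp(NumericVector p, NumericVector q, NumericMatrix cost,
                int max_iter = 100000) {
    const int n = p.size(), m = q.size();
    if (cost.nrow() != n || cost.ncol() != m)
        stop("cost matrix dimensions do not match the measure supports");
    const int nv = n + m;          // tree vertices: rows 0..n-1, cols n..n+m-1
    const int nb = n + m - 1;      // basis size

    std::vector<BasisCell> basis;
    basis.reserve(nb);

    // north-west corner initial basic feasible solution
    {
        std::vector<double> rp(p.begin(), p.end()), rq(q.begin(), q.end());
        int i = 0, j = 0;
        while (true) {
            double x = std::min(rp[i], rq[j]);
            if (x < 0) x = 0;
            basis.push_back({i, j, x});
            rp[i] -= x;
            rq[j] -= x;
            if (i == n - 1 && j == m - 1) break;
            if (i == n - 1) ++j;
            else if (j == m - 1) ++i;
            else if (rp[i] <= rq[j]) ++i;
            else ++j;
        }
    }

    const double tol = 1e-11;
    std::vector<double> u(n), v(m);
    std::vector<char> in_basis(static_cast<size_t>(n) * m, 0);
    for (auto &b : basis) in_basis[static_cast<size_t>(b.i) * m + b.j] = 1;

    // flat adjacency scratch: each basis edge appears once per endpoint
    std::vector<int> deg(nv), off(nv + 1), adj(2 * nb);
    std::vector<int> stack_buf(nv), par_edge(nv), par_vtx(nv);
    std::vector<char> seen(nv);
    std::vector<int> path;
    path.reserve(nv);

    int iter = 0;
    for (; iter < max_iter; ++iter) {
        // rebuild tree adjacency (counting sort over basis cells)
        std::fill(deg.begin(), deg.end(), 0);
        for (int k = 0; k < nb; ++k) {
            ++deg[basis[k].i];
            ++deg[n + basis[k].j];
        }
        off[0] = 0;
        for (int t = 0; t < nv; ++t) off[t + 1] = off[t] + deg[t];
        {
            std::vector<int> pos(off.begin(), off.end() - 1);
            for (int k = 0; k < nb; ++k) {
                adj[pos[basis[k].i]++] = k;
                adj[pos[n + basis[k].j]++] = k;
            }
        }

        // duals by DFS from row 0 over the basis tree
        std::fill(seen.begin(), seen.end(), 0);
        u[0] = 0.0;
        seen[0] = 1;
        int top = 0;
        stack_buf[top++] = 0;
        while (top > 0) {
            int vtx = stack_buf[--top];
            for (int t = off[vtx]; t < off[vtx + 1]; ++t) {
                int k = adj[t];
                int other = (vtx < n) ? n + basis[k].j : basis[k].i;
                if (seen[other]) continue;
                double c = cost(basis[k].i, basis[k].j);
                if (other >= n) v[other - n] = c - u[basis[k].i];
                else u[other] = c - v[basis[k].j];
                seen[other] = 1;
                stack_buf[top++] = other;
            }
        }

        // entering cell: most negative reduced cost, lowest (i,j) on ties
        int ei = -1, ej = -1;
        double best = -tol;
        for (int i = 0; i < n; ++i) {
            const double ui = u[i];
            for (int j = 0; j < m; ++j) {
                if (in_basis[static_cast<size_t>(i) * m + j]) continue;
                double rc = cost(i, j) - ui - v[j];
                if (rc < best - 1e-15) {
                    best = rc;
                    ei = i;
                    ej = j;
                }
            }
        }
        if (ei < 0) break; // optimal

        // cycle: unique tree path row ei -> col ej, plus the entering edge
        std::fill(seen.begin(), seen.end(), 0);
        seen[ei] = 1;
        par_vtx[ei] = -1;
        top = 0;
        stack_buf[top++] = ei;
        while (top > 0 && !seen[n + ej]) {
            int vtx = stack_buf[--top];
            for (int t = off[vtx]; t < off[vtx + 1]; ++t) {
                int k = adj[t];
                int other = (vtx < n) ? n + basis[k].j : basis[k].i;
                if (seen[other]) continue;
                seen[other] = 1;
                par_edge[other] = k;
                par_vtx[other] = vtx;
                stack_buf[top++] = other;
            }
        }
        if (!seen[n + ej]) stop("internal error: basis tree disconnected");

        // walk back col ej -> row ei; edges alternate -,+,-,... because the
        // entering edge (ei,ej) carries +
        path.clear();
        for (int vtx = n + ej; vtx != ei; vtx = par_vtx[vtx])
            path.push_back(par_edge[vtx]);
        double theta = R_PosInf;
        int leave = -1;
        for (size_t s = 0; s < path.size(); s += 2) { // minus positions
            if (basis[path[s]].x < theta) {
                theta = basis[path[s]].x;
                leave = path[s];
            }
        }
        for (size_t s = 0; s < path.size(); ++s)
            basis[path[s]].x += (s % 2 == 0) ? -theta : theta;

        in_basis[static_cast<size_t>(basis[leave].i) * m + basis[leave].j] = 0;
        in_basis[static_cast<size_t>(ei) * m + ej] = 1;
        basis[leave].i = ei;
        basis[leave].j = ej;
        basis[leave].x = theta;
    }
    if (iter >= max_iter)
        stop("transportation simplex failed to converge (iteration cap hit)");

    NumericMatrix plan(n, m);
    double total = 0.0;
    for (auto &b : basis) {
        double x = (b.x < 0 && b.x > -1e-12) ? 0.0 : b.x;
        plan(b.i, b.j) += x;
        total += cost(b.i, b.j) * x;
    }
    return List::create(_["cost"] = total, _["plan"] = plan,
                        _["iterations"] = iter);
}
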