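// Low-level numerical kernels: dilated convolution (forward/backward) via
// im2col + BLAS gemm, multi-source Dijkstra for geodesic distances,
// connected-component labelling and nearest/linear resampling.
// Arrays are column-major R arrays with spatial dims (nx, ny, nz) and an
// optional trailing channel dim; 2D images travel as nz = 1.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <cmath>

// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the (transposed) im2col matrix: rows index output voxels, columns
// index (channel, kernel offset), so inner copies are contiguous in memory.
// Zero padding keeps the output resolution equal to the input.
static arma::mat im2col3(const double* x, int nx, int ny, int nz, int cin,
                         int kx, int ky, int kz, int dx, int dy, int dz) {
  const size_t nvox = static_cast<size_t>(nx) * ny * nz;
  const int krn = kx * ky * kz;
  arma::mat col(nvox, static_cast<size_t>(cin) * krn, arma::fill::zeros);
  const int px = (kx - 1) * dx / 2;
  const int py = (ky - 1) * dy / 2;
  const int pz = (kz - 1) * dz / 2;
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + static_cast<size_t>(c) * nvox;
    for (int ok = 0; ok < kz; ++ok) {
      for (int oj = 0; oj < ky; ++oj) {
        for (int oi = 0; oi < kx; ++oi) {
          double* dst0 = col.colptr(c * krn + (ok * ky + oj) * kx + oi);
          const int si = oi * dx - px;
          const int sj = oj * dy - py;
          const int sk = ok * dz - pz;
          for (int k = 0; k < nz; ++k) {
            const int zk = k + sk;
            if (zk < 0 || zk >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              const int yj = j + sj;
              if (yj < 0 || yj >= ny) continue;
              const int i0 = std::max(0, -si);
              const int i1 = std::min(nx, nx - si);
              if (i1 <= i0) continue;
              const double* src = xc + (static_cast<size_t>(zk) * ny + yj) * nx + (i0 + si);
              double* dst = dst0 + (static_cast<size_t>(k) * ny + j) * nx + i0;
              std::memcpy(dst, src, sizeof(double) * (i1 - i0));
            }
          }
        }
      }
    }
  }
  return col;
}

// Forward dilated convolution with resolution-preserving zero padding.
// x: numeric vector holding an (nx, ny, nz, cin) array; W: (cin*kx*ky*kz) x cout.
// Returns an (nx, ny, nz, cout) array as a numeric vector.
// [[Rcpp::export(name = ".conv_fwd")]]
NumericVector conv_fwd(NumericVector x, IntegerVector dim, NumericMatrix W,
                       NumericVector b, IntegerVector kernel, IntegerVector dilation) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], cin = dim[3];
  const int nvox = nx * ny * nz;
  const int cout = W.ncol();
  arma::mat col = im2col3(x.begin(), nx, ny, nz, cin,
                          kernel[0], kernel[1], kernel[2],
                          dilation[0], dilation[1], dilation[2]);
  const arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);
  arma::mat out = col * Wm;  // nvox x cout
  for (int c = 0; c < cout; ++c) out.col(c) += b[c];
  NumericVector res(static_cast<R_xlen_t>(nvox) * cout);
  std::copy(out.memptr(), out.memptr() + out.n_elem, res.begin());
  res.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return res;
}

// Backward pass: given upstream gradient gout (nx, ny, nz, cout), return
// gradients w.r.t. the input, the weights and the bias.
// [[Rcpp::export(name = ".conv_bwd")]]
List conv_bwd(NumericVector x, IntegerVector dim, NumericMatrix W,
              NumericVector gout, IntegerVector kernel, IntegerVector dilation) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], cin = dim[3];
  const int nvox = nx * ny * nz;
  const int cout = W.ncol();
  const int kx = kernel[0], ky = kernel[1], kz = kernel[2];
  const int dx = dilation[0], dy = dilation[1], dz = dilation[2];
  const int krn = kx * ky * kz;

  arma::mat col = im2col3(x.begin(), nx, ny, nz, cin, kx, ky, kz, dx, dy, dz);
  const arma::mat G(gout.begin(), nvox, cout, false);
  const arma::mat Wm(W.begin(), W.nrow(), W.ncol(), false);

  arma::mat gW = col.t() * G;             // (cin*krn) x cout
  arma::rowvec gb = arma::sum(G, 0);      // 1 x cout
  arma::mat gcol = G * Wm.t();            // nvox x (cin*krn)

  // col2im: scatter-add gcol back onto the input grid (reverse of im2col3).
  NumericVector gx(static_cast<R_xlen_t>(nvox) * cin);
  const int px = (kx - 1) * dx / 2;
  const int py = (ky - 1) * dy / 2;
  const int pz = (kz - 1) * dz / 2;
  for (int c = 0; c < cin; ++c) {
    double* gxc = gx.begin() + static_cast<size_t>(c) * nvox;
    for (int ok = 0; ok < kz; ++ok) {
      for (int oj = 0; oj < ky; ++oj) {
        for (int oi = 0; oi < kx; ++oi) {
          const double* gc = gcol.colptr(c * krn + (ok * ky + oj) * kx + oi);
          const int si = oi * dx - px;
          const int sj = oj * dy - py;
          const int sk = ok * dz - pz;
          for (int k = 0; k < nz; ++k) {
            const int zk = k + sk;
            if (zk < 0 || zk >= nz) continue;
            for (int j = 0; j < ny; ++j) {
              const int yj = j + sj;
              if (yj < 0 || yj >= ny) continue;
              const int i0 = std::max(0, -si);
              const int i1 = std::min(nx, nx - si);
              const double* src = gc + (static_cast<size_t>(k) * ny + j) * nx + i0;
              double* dst = gxc + (static_cast<size_t>(zk) * ny + yj) * nx + (i0 + si);
              for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  NumericMatrix gWr(gW.n_rows, gW.n_cols);
  std::copy(gW.memptr(), gW.memptr() + gW.n_elem, gWr.begin());
  NumericVector gbr(cout);
  for (int c = 0; c < cout; ++c) gbr[c] = gb[c];
  return List::create(_["gx"] = gx, _["gW"] = gWr, _["gb"] = gbr);
}

// Exact binary min-cut for the submodular CRF by Dinic's max-flow on the
// pixel graph. Terminal capacities use the standard reduction: node i gets a
// single terminal arc of capacity |u0[i] - u1[i]| (source arc if labelling i
// background is the costlier choice at the terminal, sink arc otherwise);
// each unordered neighbour pair (i, j) becomes a residual arc pair of equal
// capacity w. Returns 1 for nodes on the source side (foreground).
struct DinicGraph {
  std::vector<int> head, nxt, to;
  std::vector<double> cap;
  std::vector<int> level, it;
  int n;
  explicit DinicGraph(int n_) : head(n_, -1), n(n_) {}
  void add_pair(int u, int v, double c_uv, double c_vu) {
    nxt.push_back(head[u]); head[u] = to.size(); to.push_back(v); cap.push_back(c_uv);
    nxt.push_back(head[v]); head[v] = to.size(); to.push_back(u); cap.push_back(c_vu);
  }
  bool bfs(int s, int t) {
    level.assign(n, -1);
    std::vector<int> q; q.reserve(n);
    q.push_back(s); level[s] = 0;
    for (size_t qi = 0; qi < q.size(); ++qi) {
      int u = q[qi];
      for (int e = head[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] < 0) {
          level[to[e]] = level[u] + 1;
          q.push_back(to[e]);
        }
      }
    }
    return level[t] >= 0;
  }
  // iterative augmenting-path search on the level graph (no recursion)
  double augment(int s, int t) {
    std::vector<int> path;  // arc indices from s to current node
    int u = s;
    while (true) {
      if (u == t) {
        double f = R_PosInf;
        for (size_t k = 0; k < path.size(); ++k) f = std::min(f, cap[path[k]]);
        for (size_t k = 0; k < path.size(); ++k) {
          cap[path[k]] -= f;
          cap[path[k] ^ 1] += f;
        }
        return f;
      }
      bool advanced = false;
      for (int& e = it[u]; e != -1; e = nxt[e]) {
        if (cap[e] > 1e-12 && level[to[e]] == level[u] + 1) {
          path.push_back(e);
          u = to[e];
          advanced = true;
          break;
        }
      }
      if (!advanced) {
        level[u] = -1;  // dead end: prune from level graph
        if (u == s) return 0.0;
        u = to[path.back() ^ 1];
        path.pop_back();
      }
    }
  }
  void run(int s, int t) {
    while (bfs(s, t)) {
      it = head;
      while (augment(s, t) > 0) {}
    }
  }
};

// [[Rcpp::export(name = ".graph_cut_cpp")]]
IntegerVector graph_cut_cpp(NumericVector u0, NumericVector u1,
                            IntegerVector pi, IntegerVector pj,
                            NumericVector w) {
  const int n = u0.size();
  const int s = n, t = n + 1;
  DinicGraph g(n + 2);
  for (int v = 0; v < n; ++v) {
    const double d = u0[v] - u1[v];
    if (d > 0) g.add_pair(s, v, d, 0.0);       // cut when v takes label 0
    else if (d < 0) g.add_pair(v, t, -d, 0.0); // cut when v takes label 1
  }
  for (int k = 0; k < pi.size(); ++k) {
    g.add_pair(pi[k], pj[k], w[k], w[k]);
  }
  g.run(s, t);
  // source side of the min cut = residual-reachable from s
  IntegerVector lab(n, 0);
  std::vector<char> seen(n + 2, 0);
  std::vector<int> q; q.push_back(s); seen[s] = 1;
  for (size_t qi = 0; qi < q.size(); ++qi) {
    int u = q[qi];
    for (int e = g.head[u]; e != -1; e = g.nxt[e]) {
      if (g.cap[e] > 1e-12 && !seen[g.to[e]]) {
        seen[g.to[e]] = 1;
        q.push_back(g.to[e]);
      }
    }
  }
  for (int v = 0; v < n; ++v) lab[v] = seen[v] ? 1 : 0;
  return lab;
}

// Multi-source Dijkstra on the 4/6-connected pixel graph with hybrid step
// cost sqrt((spacing*|dx|)^2 + (gamma*dI)^2). seeds are 0-based voxel indices.
// [[Rcpp::export(name = ".geodesic_cpp")]]
NumericVector geodesic_cpp(NumericVector img, IntegerVector dim,
                           IntegerVector seeds, double spacing, double gamma) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  std::vector<double> dist(n, R_PosInf);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < seeds.size(); ++s) {
    const int v = seeds[s];
    if (dist[v] > 0.0) { dist[v] = 0.0; pq.push(Node(0.0, v)); }
  }
  const int offs[3] = {1, nx, nx * ny};
  while (!pq.empty()) {
    const Node top = pq.top(); pq.pop();
    const double d = top.first;
    const int v = top.second;
    if (d > dist[v]) continue;
    const int i = v % nx;
    const int j = (v / nx) % ny;
    const int k = v / (nx * ny);
    const int coord[3] = {i, j, k};
    const int ext[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      for (int sgn = -1; sgn <= 1; sgn += 2) {
        const int ca = coord[a] + sgn;
        if (ca < 0 || ca >= ext[a]) continue;
        const int u = v + sgn * offs[a];
        const double di = gamma * (img[u] - img[v]);
        const double step = std::sqrt(spacing * spacing + di * di);
        if (dist[v] + step < dist[u]) {
          dist[u] = dist[v] + step;
          pq.push(Node(dist[u], u));
        }
      }
    }
  }
  NumericVector out(n);
  std::copy(dist.begin(), dist.end(), out.begin());
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Connected components of a binary mask under 4/6-connectivity.
// Returns integer labels 1..ncomp (0 = background), same shape as input.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  const int offs[3] = {1, nx, nx * ny};
  for (int v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || lab[v0] != 0) continue;
    ++next;
    lab[v0] = next;
    stack.push_back(v0);
    while (!stack.empty()) {
      const int v = stack.back(); stack.pop_back();
      const int coord[3] = {v % nx, (v / nx) % ny, v / (nx * ny)};
      const int ext[3] = {nx, ny, nz};
      for (int a = 0; a < 3; ++a) {
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          const int ca = coord[a] + sgn;
          if (ca < 0 || ca >= ext[a]) continue;
          const int u = v + sgn * offs[a];
          if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}

// Resample an (nx, ny, nz) array to out_dim with pixel-centre alignment.
// method: 0 = nearest neighbour, 1 = trilinear.
// [[Rcpp::export(name = ".resample_cpp")]]
NumericVector resample_cpp(NumericVector x, IntegerVector dim,
                           IntegerVector out_dim, int method) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out(static_cast<R_xlen_t>(ox) * oy * oz);
  const double sx = static_cast<double>(nx) / ox;
  const double sy = static_cast<double>(ny) / oy;
  const double sz = static_cast<double>(nz) / oz;
  for (int k = 0; k < oz; ++k) {
    const double zc = (k + 0.5) * sz - 0.5;
    for (int j = 0; j < oy; ++j) {
      const double yc = (j + 0.5) * sy - 0.5;
      for (int i = 0; i < ox; ++i) {
        const double xc = (i + 0.5) * sx - 0.5;
        double val;
        if (method == 0) {
          const int xi = std::min(nx - 1, std::max(0, static_cast<int>(std::lround(xc))));
          const int yi = std::min(ny - 1, std::max(0, static_cast<int>(std::lround(yc))));
          const int zi = std::min(nz - 1, std::max(0, static_cast<int>(std::lround(zc))));
          val = x[(static_cast<size_t>(zi) * ny + yi) * nx + xi];
        } else {
          const int x0 = std::min(nx - 1, std::max(0, static_cast<int>(std::floor(xc))));
          const int y0 = std::min(ny - 1, std::max(0, static_cast<int>(std::floor(yc))));
          const int z0 = std::min(nz - 1, std::max(0, static_cast<int>(std::floor(zc))));
          const int x1 = std::min(nx - 1, x0 + 1);
          const int y1 = std::min(ny - 1, y0 + 1);
          const int z1 = std::min(nz - 1, z0 + 1);
          const double fx = std::min(1.0, std::max(0.0, xc - x0));
          const double fy = std::min(1.0, std::max(0.0, yc - y0));
          const double fz = std::min(1.0, std::max(0.0, zc - z0));
          double acc = 0.0;
          for (int c = 0; c < 8; ++c) {
            const int xi = (c & 1) ? x1 : x0;
            const int yi = (c & 2) ? y1 : y0;
            const int zi = (c & 4) ? z1 : z0;
            const double w = ((c & 1) ? fx : 1.0 - fx) *
                             ((c & 2) ? fy : 1.0 - fy) *
                             ((c & 4) ? fz : 1.0 - fz);
            acc += w * x[(static_cast<size_t>(zi) * ny + yi) * nx + xi];
          }
          val = acc;
        }
        out[(static_cast<size_t>(k) * oy + j) * ox + i] = val;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}
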