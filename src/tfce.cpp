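#include <Rcpp.h>
#include <vector>
#include <stack>
using namespace Rcpp;

// neighbour offsets for 6- or 26-connectivity on a 3-D grid
static std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// label connected components of a logical mask; 0 = background
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  auto off = neighbour_offsets(connectivity);
  int next = 0;
  std::stack<int> todo;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || labels[i]) continue;
    labels[i] = ++next;
    todo.push(i);
    while (!todo.empty()) {
      int cur = todo.top(); todo.pop();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (auto &d : off) {
        int x = cx + d[0], y = cy + d[1], z = cz + d[2];
        if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
          continue;
        int j = x + nx * (y + ny * z);
        if (mask[j] && !labels[j]) { labels[j] = next; todo.push(j); }
      }
    }
  }
  return labels;
}

// threshold-free cluster enhancement of a non-negative statistic field:
// tfce(v) = sum_{h = dh, 2dh, ... <= stat(v)} extent(v, h)^E * h^H * dh
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims,
                       double E, double H, double dh,
                       int connectivity = 26) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n, 0.0);
  double mx = 0.0;
  for (int i = 0; i < n; ++i)
    if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0 || dh <= 0.0) return out;
  auto off = neighbour_offsets(connectivity);
  std::vector<int> labels(n), size;
  std::stack<int> todo;
  for (double h = dh; h <= mx + 1e-12; h += dh) {
    std::fill(labels.begin(), labels.end(), 0);
    size.assign(1, 0);
    int next = 0;
    for (int i = 0; i < n; ++i) {
      if (stat[i] < h || labels[i]) continue;
      labels[i] = ++next;
      size.push_back(1);
      todo.push(i);
      while (!todo.empty()) {
        int cur = todo.top(); todo.pop();
        int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
        for (auto &d : off) {
          int x = cx + d[0], y = cy + d[1], z = cz + d[2];
          if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
            continue;
          int j = x + nx * (y + ny * z);
          if (stat[j] >= h && !labels[j]) {
            labels[j] = next; ++size[next]; todo.push(j);
          }
        }
      }
    }
    double hh = std::pow(h, H) * dh;
    std::vector<double> inc(next + 1, 0.0);
    for (int l = 1; l <= next; ++l)
      inc[l] = std::pow((double)size[l], E) * hh;
    for (int i = 0; i < n; ++i)
      if (labels[i]) out[i] += inc[labels[i]];
  }
  return out;
}
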