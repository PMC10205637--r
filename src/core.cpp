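#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <vector>
#include <string>
using namespace Rcpp;

// 64-bit FNV-1a over the UTF-8 bytes of each string, rendered as 16 hex
// characters. Used both as the identifier digest (stand-in for the
// undisclosed production hash) and for file checksums in run manifests.
// [[Rcpp::export(name = ".fnv1a64")]]
CharacterVector fnv1a64(CharacterVector x) {
  const uint64_t prime = 1099511628211ULL;
  const uint64_t offset = 14695981039346656037ULL;
  R_xlen_t n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (R_xlen_t i = 0; i < n; ++i) {
    if (x[i] == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(x[i]);
    uint64_t h = offset;
    for (const unsigned char *p = (const unsigned char *)s; *p; ++p) {
      h ^= (uint64_t)(*p);
      h *= prime;
    }
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];  // path halving
    i = parent[i];
  }
  return i;
}

// Connected components of a graph on nodes 1..n via a disjoint-set forest
// with path compression and union by size. `from`/`to` are 1-based node
// indices (parallel edge list; duplicates and self-loops allowed).
// Returns the 1-based index of the smallest node in each node's component,
// so labels are deterministic and independent of edge order.
// [[Rcpp::export(name = ".uf_components")]]
IntegerVector uf_components(IntegerVector from, IntegerVector to, int n) {
  if (n < 0) stop("n must be non-negative");
  std::vector<int> parent(n), size(n, 1);
  for (int i = 0; i < n; ++i) parent[i] = i;
  R_xlen_t m = from.size();
  if (to.size() != m) stop("edge vectors must have equal length");
  for (R_xlen_t e = 0; e < m; ++e) {
    int a = from[e], b = to[e];
    if (a == NA_INTEGER || b == NA_INTEGER) stop("NA node index in edge list");
    if (a < 1 || a > n || b < 1 || b > n) stop("node index out of range");
    int ra = uf_find(parent, a - 1), rb = uf_find(parent, b - 1);
    if (ra == rb) continue;
    if (size[ra] < size[rb]) std::swap(ra, rb);
    parent[rb] = ra;
    size[ra] += size[rb];
  }
  // smallest member per root
  std::vector<int> rep(n, -1);
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    if (rep[r] < 0) rep[r] = i;  // nodes visited in increasing order
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rep[uf_find(parent, i)] + 1;
  return out;
}
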