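// Core combinatorial engine: signed Gauss codes of link diagrams, Reidemeister
// reduction, HOMFLYPT skein recursion, generic projection of 3-D polygons,
// DT-code realizability via rotation-system planarity, and the equilateral
// random polygon sampler.  Exposed to R through Rcpp; all user-facing surfaces
// live in R.
//
// Diagram encoding ("gauss list" at the R interface):
//   comps : list of integer vectors, one per link component; each event is
//           4*crossing_id + over  (crossing_id >= 0, over in {0,1})
//   sign  : integer vector indexed by crossing_id + 1 (values +1/-1, 0 = dead)
//   freeloops : crossing-free circles split off by reductions/smoothings
//
// Skein convention (lmpoly lineage):  l*P(L+) + (1/l)*P(L-) + m*P(L0) = 0,
// unknot = 1, so a k-component descending unlink has P = (-(l+1/l)/m)^(k-1).
// Mirroring a link inverts l.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <complex>
#include <cstdint>
#include <map>
#include <numeric>
#include <set>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

typedef std::pair<int, int> Expo;          // (exponent of l, exponent of m)
typedef std::map<Expo, long long> Poly;    // sparse, ordered for canonical output

struct Diag {
  std::vector<std::vector<int>> comp;  // events: 4*id + over
  std::vector<int8_t> sign;            // indexed by crossing id
  int freeloops = 0;
};

static inline int ev_id(int e) { return e >> 2; }
static inline int ev_over(int e) { return e & 1; }
static inline int ev_make(int id, int over) { return 4 * id + over; }

// ----------------------------------------------------------------------------
// polynomial helpers
// ----------------------------------------------------------------------------

static void poly_add(Poly &a, const Poly &b, long long f, int dl, int dm) {
  for (const auto &kv : b) {
    Expo k(kv.first.first + dl, kv.first.second + dm);
    long long v = a[k] + f * kv.second;
    if (v == 0) a.erase(k); else a[k] = v;
  }
}

static long long binom(int n, int k) {
  long long r = 1;
  for (int i = 0; i < k; ++i) r = r * (n - i) / (i + 1);
  return r;
}

// (-(l + 1/l)/m)^k expanded directly
static Poly delta_pow(int k) {
  Poly p;
  if (k == 0) { p[Expo(0, 0)] = 1; return p; }
  long long s = (k % 2 == 0) ? 1 : -1;
  for (int i = 0; i <= k; ++i) p[Expo(k - 2 * i, -k)] = s * binom(k, i);
  return p;
}

static std::string poly_string(const Poly &p) {
  if (p.empty()) return "0";
  std::string s;
  for (const auto &kv : p) {
    if (!s.empty()) s += "|";
    s += std::to_string(kv.first.first) + "," + std::to_string(kv.first.second) +
         ":" + std::to_string(kv.second);
  }
  return s;
}

static long long parse_ll(const std::string &s) {
  long long v = 0, sgn = 1;
  size_t i = 0;
  if (i < s.size() && (s[i] == '-' || s[i] == '+')) { if (s[i] == '-') sgn = -1; ++i; }
  for (; i < s.size() && s[i] >= '0' && s[i] <= '9'; ++i) v = v * 10 + (s[i] - '0');
  return sgn * v;
}

static Poly poly_parse(const std::string &s) {
  Poly p;
  if (s == "0" || s.empty()) return p;
  size_t pos = 0;
  while (pos < s.size()) {
    size_t bar = s.find('|', pos);
    if (bar == std::string::npos) bar = s.size();
    std::string term = s.substr(pos, bar - pos);
    size_t c1 = term.find(','), c2 = term.find(':');
    int le = (int)parse_ll(term.substr(0, c1));
    int me = (int)parse_ll(term.substr(c1 + 1, c2 - c1 - 1));
    long long co = parse_ll(term.substr(c2 + 1));
    if (co != 0) p[Expo(le, me)] = co;
    pos = bar + 1;
  }
  return p;
}

// ----------------------------------------------------------------------------
// R1/R2 reduction on gauss codes
//
// Both moves act on arcs free of other crossings, so anything trapped in the
// eliminated monogon/bigon is a split sublink and the move preserves link type.
// ----------------------------------------------------------------------------

static void erase_positions(std::vector<int> &v, std::vector<int> pos) {
  std::sort(pos.begin(), pos.end());
  for (int k = (int)pos.size() - 1; k >= 0; --k) v.erase(v.begin() + pos[k]);
}

static void drop_empty(Diag &d) {
  std::vector<std::vector<int>> keep;
  for (auto &c : d.comp) {
    if (c.empty()) d.freeloops++; else keep.push_back(std::move(c));
  }
  d.comp.swap(keep);
}

static bool reduce_R1_once(Diag &d) {
  for (size_t ci = 0; ci < d.comp.size(); ++ci) {
    std::vector<int> &c = d.comp[ci];
    int L = (int)c.size();
    for (int i = 0; i < L; ++i) {
      int j = (i + 1) % L;
      if (i != j && ev_id(c[i]) == ev_id(c[j])) {
        d.sign[ev_id(c[i])] = 0;
        erase_positions(c, {i, j});
        drop_empty(d);
        return true;
      }
    }
  }
  return false;
}

static bool reduce_R2_once(Diag &d) {
  // locate both events of every crossing
  std::unordered_map<int, std::array<std::pair<int,int>,2>> where;
  std::unordered_map<int, int> seen;
  for (size_t ci = 0; ci < d.comp.size(); ++ci)
    for (size_t p = 0; p < d.comp[ci].size(); ++p) {
      int id = ev_id(d.comp[ci][p]);
      where[id][seen[id]++] = {(int)ci, (int)p};
    }
  for (size_t ci = 0; ci < d.comp.size(); ++ci) {
    std::vector<int> &c = d.comp[ci];
    int L = (int)c.size();
    if (L < 2) continue;
    for (int i = 0; i < L; ++i) {
      int j = (i + 1) % L;
      int a = c[i], b = c[j];
      if (ev_id(a) == ev_id(b)) continue;
      if (ev_over(a) != ev_over(b)) continue;  // need same strand both over/under
      // partner events (the complementary passages of a and b)
      auto pa = (where[ev_id(a)][0] == std::make_pair((int)ci, i)) ? where[ev_id(a)][1]
                                                                   : where[ev_id(a)][0];
      auto pb = (where[ev_id(b)][0] == std::make_pair((int)ci, j)) ? where[ev_id(b)][1]
                                                                   : where[ev_id(b)][0];
      if (pa.first != pb.first) continue;
      std::vector<int> &c2 = d.comp[pa.first];
      int L2 = (int)c2.size();
      int q1 = pa.second, q2 = pb.second;
      bool adj = ((q1 + 1) % L2 == q2) || ((q2 + 1) % L2 == q1);
      if (!adj) continue;
      // ensure the four positions are distinct events
      std::set<std::pair<int,int>> uniq = {{(int)ci, i}, {(int)ci, j},
                                           {pa.first, q1}, {pb.first, q2}};
      if (uniq.size() != 4) continue;
      d.sign[ev_id(a)] = 0;
      d.sign[ev_id(b)] = 0;
      if (pa.first == (int)ci) {
        erase_positions(c, {i, j, q1, q2});
      } else {
        erase_positions(c, {i, j});
        erase_positions(c2, {q1, q2});
      }
      drop_empty(d);
      return true;
    }
  }
  return false;
}

static void reduce_R1R2(Diag &d) {
  bool ch = true;
  while (ch) {
    ch = false;
    while (reduce_R1_once(d)) ch = true;
    if (reduce_R2_once(d)) ch = true;
  }
}

static int n_crossings(const Diag &d) {
  int n = 0;
  for (auto s : d.sign) if (s != 0) ++n;
  return n;
}

// ----------------------------------------------------------------------------
// canonical string key (injective on diagrams; used for memo + BFS dedup)
// ----------------------------------------------------------------------------

static std::string canon_key(const Diag &d) {
  // relabel crossings by first appearance, scanning components in stored order,
  // each component from its lexicographically-minimal rotation of raw tokens;
  // emitted as a compact byte string
  std::vector<int> starts;
  starts.reserve(d.comp.size());
  for (const auto &c : d.comp) {
    int L = (int)c.size();
    int best = 0;
    for (int s = 1; s < L; ++s)
      for (int k = 0; k < L; ++k) {
        int x = c[(s + k) % L], y = c[(best + k) % L];
        if (x != y) { if (x < y) best = s; break; }
      }
    starts.push_back(best);
  }
  std::unordered_map<int, int> lab;
  lab.reserve(d.sign.size());
  std::string out;
  out.reserve(4 * d.sign.size() + d.comp.size() + 8);
  for (size_t ci = 0; ci < d.comp.size(); ++ci) {
    const auto &c = d.comp[ci];
    int L = (int)c.size(), s = starts[ci];
    out.push_back((char)1);                       // component separator
    for (int k = 0; k < L; ++k) {
      int e = c[(s + k) % L];
      int id = ev_id(e);
      auto it = lab.find(id);
      int l;
      if (it == lab.end()) { l = (int)lab.size(); lab[id] = l; } else l = it->second;
      // label < ~16k crossings: two bytes + over bit
      out.push_back((char)(2 + (l & 127)));
      out.push_back((char)(2 + ((l >> 7) & 127) + (ev_over(e) ? 128 : 0)));
    }
  }
  out.push_back((char)1);
  std::vector<int> inv(lab.size());
  for (auto &kv : lab) inv[kv.second] = kv.first;
  for (size_t i = 0; i < inv.size(); ++i)
    out.push_back(d.sign[inv[i]] > 0 ? 'P' : 'N');
  out.push_back((char)(2 + d.freeloops));
  return out;
}

// ----------------------------------------------------------------------------
// skein operations
// ----------------------------------------------------------------------------

static void find_events(const Diag &d, int id, int &c1, int &p1, int &c2, int &p2) {
  c1 = -1; c2 = -1;
  for (size_t ci = 0; ci < d.comp.size(); ++ci)
    for (size_t p = 0; p < d.comp[ci].size(); ++p)
      if (ev_id(d.comp[ci][p]) == id) {
        if (c1 < 0) { c1 = (int)ci; p1 = (int)p; }
        else { c2 = (int)ci; p2 = (int)p; return; }
      }
}

static Diag do_switch(const Diag &d, int id) {
  Diag r = d;
  for (auto &c : r.comp)
    for (auto &e : c)
      if (ev_id(e) == id) e ^= 1;
  r.sign[id] = -r.sign[id];
  return r;
}

// oriented smoothing: delete the crossing, reconnect respecting orientation
static Diag do_smooth(const Diag &d, int id) {
  Diag r = d;
  int c1, p1, c2, p2;
  find_events(r, id, c1, p1, c2, p2);
  r.sign[id] = 0;
  if (c1 == c2) {
    // self-crossing: split one component into two
    const std::vector<int> &c = r.comp[c1];
    int L = (int)c.size();
    int a = std::min(p1, p2), b = std::max(p1, p2);
    std::vector<int> s1, s2;
    for (int k = a + 1; k < b; ++k) s1.push_back(c[k]);
    for (int k = b + 1; k < L + a; ++k) s2.push_back(c[k % L]);
    r.comp.erase(r.comp.begin() + c1);
    if (s1.empty()) r.freeloops++; else r.comp.push_back(std::move(s1));
    if (s2.empty()) r.freeloops++; else r.comp.push_back(std::move(s2));
  } else {
    // crossing between two components: merge them
    std::vector<int> &ca = r.comp[c1];
    std::vector<int> &cb = r.comp[c2];
    std::vector<int> m;
    int La = (int)ca.size(), Lb = (int)cb.size();
    for (int k = 0; k < p1; ++k) m.push_back(ca[k]);
    for (int k = 1; k < Lb; ++k) m.push_back(cb[(p2 + k) % Lb]);
    for (int k = p1 + 1; k < La; ++k) m.push_back(ca[k]);
    int hi = std::max(c1, c2), lo = std::min(c1, c2);
    r.comp.erase(r.comp.begin() + hi);
    r.comp.erase(r.comp.begin() + lo);
    if (m.empty()) r.freeloops++; else r.comp.push_back(std::move(m));
  }
  return r;
}

// first crossing whose first encounter (stored traversal order) is an underpass
static int first_bad(const Diag &d) {
  std::unordered_set<int> seen;
  for (const auto &c : d.comp)
    for (int e : c) {
      int id = ev_id(e);
      if (seen.count(id)) continue;
      seen.insert(id);
      if (!ev_over(e)) return id;
    }
  return -1;
}

struct HomflyCtx {
  std::unordered_map<std::string, Poly> memo;
  long long nodes = 0;
  long long max_nodes;
};

// persistent cross-call memo for small subdiagrams: the leaves of every skein
// tree are shared across the millions of closures a disk matrix evaluates
static std::unordered_map<std::string, Poly> g_small_memo;
static const int SMALL_MEMO_CROSSINGS = 14;
static const size_t SMALL_MEMO_CAP = 2000000;

// [[Rcpp::export(name = ".cpp_memo_size")]]
double cpp_memo_size() { return (double)g_small_memo.size(); }

static Poly homfly_rec(Diag d, HomflyCtx &ctx) {
  if (++ctx.nodes > ctx.max_nodes)
    throw std::runtime_error("HOMFLYPT recursion budget exceeded (diagram with " +
                             std::to_string(n_crossings(d)) + " crossings)");
  reduce_R1R2(d);
  int total = (int)d.comp.size() + d.freeloops;
  int nc = n_crossings(d);
  if (nc == 0) return delta_pow(std::max(0, total - 1));
  std::string key = canon_key(d);
  bool small = nc <= SMALL_MEMO_CROSSINGS;
  if (small) {
    auto it = g_small_memo.find(key);
    if (it != g_small_memo.end()) return it->second;
  }
  auto it = ctx.memo.find(key);
  if (it != ctx.memo.end()) return it->second;
  int b = first_bad(d);
  Poly res;
  if (b < 0) {
    res = delta_pow(std::max(0, total - 1));  // descending diagram: unlink
  } else {
    Poly psw = homfly_rec(do_switch(d, b), ctx);
    Poly psm = homfly_rec(do_smooth(d, b), ctx);
    if (d.sign[b] > 0) {
      // P(L+) = -l^-2 P(L-) - l^-1 m P(L0)
      poly_add(res, psw, -1, -2, 0);
      poly_add(res, psm, -1, -1, 1);
    } else {
      // P(L-) = -l^2 P(L+) - l m P(L0)
      poly_add(res, psw, -1, 2, 0);
      poly_add(res, psm, -1, 1, 1);
    }
  }
  if (small && g_small_memo.size() < SMALL_MEMO_CAP) g_small_memo[key] = res;
  else ctx.memo[key] = res;
  return res;
}

// ----------------------------------------------------------------------------
// R3 moves and budgeted simplification search
// ----------------------------------------------------------------------------

struct AdjPair {
  int comp, pos;        // pair occupies (pos, pos+1 mod L)
  int ida, idb;         // crossing ids in traversal order
  int pattern;          // 2 = both over, 0 = both under, 1 = mixed
};

static std::vector<AdjPair> adjacent_pairs(const Diag &d) {
  std::vector<AdjPair> out;
  for (size_t ci = 0; ci < d.comp.size(); ++ci) {
    const std::vector<int> &c = d.comp[ci];
    int L = (int)c.size();
    if (L < 2) continue;
    for (int i = 0; i < L; ++i) {
      int j = (i + 1) % L;
      if (i == j) continue;
      int a = c[i], b = c[j];
      if (ev_id(a) == ev_id(b)) continue;
      int pat = ev_over(a) + ev_over(b);
      out.push_back({(int)ci, i, ev_id(a), ev_id(b), pat});
    }
  }
  return out;
}

// enumerate R3 moves: three adjacent pairs covering crossings {a,b},{b,c},{a,c},
// six distinct events, with a transitive over/under pattern (one strand over
// both its crossings, one under both, one mixed)
static std::vector<Diag> r3_neighbours(const Diag &d) {
  std::vector<Diag> out;
  std::vector<AdjPair> ap = adjacent_pairs(d);
  // index adjacent pairs by their unordered crossing-id pair
  std::map<std::pair<int,int>, std::vector<int>> by_ids;
  for (size_t i = 0; i < ap.size(); ++i) {
    std::pair<int,int> key(std::min(ap[i].ida, ap[i].idb),
                           std::max(ap[i].ida, ap[i].idb));
    by_ids[key].push_back((int)i);
  }
  std::vector<std::pair<int,int>> keys;
  keys.reserve(by_ids.size());
  for (auto &kv : by_ids) keys.push_back(kv.first);
  auto try_triple = [&](int i, int j, int k) {
    const AdjPair *tri[3] = {&ap[i], &ap[j], &ap[k]};
    // six distinct event slots
    std::set<std::pair<int,int>> slots;
    for (auto *p : tri) {
      int L = (int)d.comp[p->comp].size();
      slots.insert({p->comp, p->pos});
      slots.insert({p->comp, (p->pos + 1) % L});
    }
    if (slots.size() != 6) return;
    int nover = 0, nunder = 0;
    for (auto *p : tri) {
      if (p->pattern == 2) nover++;
      if (p->pattern == 0) nunder++;
    }
    if (nover != 1 || nunder != 1) return;
    Diag r = d;
    for (auto *p : tri) {
      std::vector<int> &c = r.comp[p->comp];
      int L = (int)c.size();
      std::swap(c[p->pos], c[(p->pos + 1) % L]);
    }
    out.push_back(std::move(r));
  };
  // crossing-id triples {a,b,c} with all three sides present as adjacent pairs
  for (size_t u = 0; u < keys.size(); ++u)
    for (size_t v = u + 1; v < keys.size(); ++v) {
      int a = keys[u].first, b = keys[u].second;
      int x = keys[v].first, y = keys[v].second;
      int shared, c1, c2;
      if (x == a) { shared = a; c1 = b; c2 = y; }
      else if (x == b) { shared = b; c1 = a; c2 = y; }
      else if (y == a) { shared = a; c1 = b; c2 = x; }
      else if (y == b) { shared = b; c1 = a; c2 = x; }
      else continue;
      if (c1 == c2) continue;
      (void)shared;
      auto it = by_ids.find({std::min(c1, c2), std::max(c1, c2)});
      if (it == by_ids.end()) continue;
      // avoid triple duplication: require third key > second key in order
      std::pair<int,int> third(std::min(c1, c2), std::max(c1, c2));
      if (!(keys[v] < third)) continue;
      for (int i : by_ids[keys[u]])
        for (int j : by_ids[keys[v]])
          for (int k : it->second) try_triple(i, j, k);
    }
  return out;
}

// greedy R1/R2 to a fixed point, then breadth-first R3 exploration (bounded by
// `budget` visited diagrams) restarted whenever the crossing count drops
static Diag simplify_search(Diag d, int budget, int target = 0) {
  reduce_R1R2(d);
  if (n_crossings(d) <= target || budget <= 0) return d;
  int visited = 0;
  bool improved = true;
  while (improved && visited < budget && n_crossings(d) > target) {
    improved = false;
    std::unordered_set<std::string> seen;
    std::vector<Diag> frontier = {d};
    seen.insert(canon_key(d));
    while (!frontier.empty() && visited < budget && !improved) {
      std::vector<Diag> next;
      for (Diag &cur : frontier) {
        if (visited >= budget || improved) break;
        for (Diag &nb : r3_neighbours(cur)) {
          if (visited >= budget) break;
          Diag red = nb;
          reduce_R1R2(red);
          ++visited;
          if (n_crossings(red) < n_crossings(d)) {
            d = red;
            improved = true;
            break;
          }
          std::string key = canon_key(nb);
          if (seen.insert(key).second) next.push_back(std::move(nb));
        }
      }
      frontier.swap(next);
    }
  }
  return d;
}

// ----------------------------------------------------------------------------
// R interface: diagram conversion
// ----------------------------------------------------------------------------

static Diag from_R(const List &diagram) {
  Diag d;
  List comps = diagram["comps"];
  IntegerVector sg = diagram["sign"];
  IntegerVector ov;
  d.sign.assign(sg.size(), 0);
  for (int i = 0; i < sg.size(); ++i) d.sign[i] = (int8_t)sg[i];
  for (int ci = 0; ci < comps.size(); ++ci) {
    IntegerMatrix m = comps[ci];  // 2 x L: row 0 = crossing id (1-based), row 1 = over
    std::vector<int> c(m.ncol());
    for (int k = 0; k < m.ncol(); ++k) c[k] = ev_make(m(0, k) - 1, m(1, k));
    d.comp.push_back(std::move(c));
  }
  if (diagram.containsElementNamed("freeloops"))
    d.freeloops = as<int>(diagram["freeloops"]);
  return d;
}

static List to_R(const Diag &d0) {
  // compact crossing ids to 1..c in first-appearance order
  Diag d = d0;
  std::unordered_map<int, int> lab;
  for (auto &c : d.comp)
    for (int e : c) {
      int id = ev_id(e);
      if (!lab.count(id)) lab[id] = (int)lab.size();
    }
  List comps(d.comp.size());
  for (size_t ci = 0; ci < d.comp.size(); ++ci) {
    IntegerMatrix m(2, d.comp[ci].size());
    for (size_t k = 0; k < d.comp[ci].size(); ++k) {
      m(0, k) = lab[ev_id(d.comp[ci][k])] + 1;
      m(1, k) = ev_over(d.comp[ci][k]);
    }
    comps[ci] = m;
  }
  IntegerVector sg(lab.size());
  for (auto &kv : lab) sg[kv.second] = d.sign[kv.first];
  return List::create(_["comps"] = comps, _["sign"] = sg,
                      _["freeloops"] = d.freeloops);
}

// [[Rcpp::export(name = ".cpp_reduce")]]
List cpp_reduce(List diagram) {
  Diag d = from_R(diagram);
  reduce_R1R2(d);
  return to_R(d);
}

// [[Rcpp::export(name = ".cpp_simplify")]]
List cpp_simplify(List diagram, int budget = 1000) {
  Diag d = from_R(diagram);
  return to_R(simplify_search(std::move(d), budget));
}

// [[Rcpp::export(name = ".cpp_homfly")]]
String cpp_homfly(List diagram, double max_nodes = 2e5) {
  Diag d = from_R(diagram);
  HomflyCtx ctx;
  ctx.max_nodes = (long long)max_nodes;
  Poly p = homfly_rec(std::move(d), ctx);
  return poly_string(p);
}

// [[Rcpp::export(name = ".cpp_poly_product")]]
String cpp_poly_product(StringVector polys) {
  Poly acc;
  acc[Expo(0, 0)] = 1;
  for (int i = 0; i < polys.size(); ++i) {
    Poly q = poly_parse(std::string(polys[i]));
    Poly r;
    for (const auto &a : acc)
      for (const auto &b : q) {
        Expo k(a.first.first + b.first.first, a.first.second + b.first.second);
        long long v = r[k] + a.second * b.second;
        if (v == 0) r.erase(k); else r[k] = v;
      }
    acc.swap(r);
  }
  return poly_string(acc);
}

// substitute l -> 1/l (mirror image)
// [[Rcpp::export(name = ".cpp_poly_mirror")]]
String cpp_poly_mirror(String poly) {
  Poly p = poly_parse(std::string(poly));
  Poly q;
  for (const auto &kv : p) q[Expo(-kv.first.first, kv.first.second)] = kv.second;
  return poly_string(q);
}

// evaluate at complex (l, m); returns (re, im)
// [[Rcpp::export(name = ".cpp_poly_eval")]]
NumericVector cpp_poly_eval(String poly, double lr, double li, double mr, double mi) {
  Poly p = poly_parse(std::string(poly));
  std::complex<double> l(lr, li), m(mr, mi), acc(0, 0);
  for (const auto &kv : p)
    acc += (double)kv.second * std::pow(l, kv.first.first) * std::pow(m, kv.first.second);
  return NumericVector::create(acc.real(), acc.imag());
}

// ----------------------------------------------------------------------------
// projection of a closed 3-D polygon to a signed crossing code
// ----------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_project")]]
List cpp_project(NumericMatrix verts, NumericVector dir, double tol = 1e-9) {
  int n = verts.nrow();
  // orthonormal frame (u, v, w) with w = dir, u x v = w
  double w[3] = {dir[0], dir[1], dir[2]};
  double nw = std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
  for (double &x : w) x /= nw;
  int ax = 0;
  for (int k = 1; k < 3; ++k) if (std::abs(w[k]) < std::abs(w[ax])) ax = k;
  double e[3] = {0, 0, 0};
  e[ax] = 1;
  double u[3] = {e[1]*w[2] - e[2]*w[1], e[2]*w[0] - e[0]*w[2], e[0]*w[1] - e[1]*w[0]};
  double nu = std::sqrt(u[0]*u[0] + u[1]*u[1] + u[2]*u[2]);
  for (double &x : u) x /= nu;
  double v[3] = {w[1]*u[2] - w[2]*u[1], w[2]*u[0] - w[0]*u[2], w[0]*u[1] - w[1]*u[0]};

  // project and rescale to unit bounding radius (scale-free tolerances)
  std::vector<double> X(n), Y(n), Z(n);
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) {
    X[i] = verts(i,0)*u[0] + verts(i,1)*u[1] + verts(i,2)*u[2];
    Y[i] = verts(i,0)*v[0] + verts(i,1)*v[1] + verts(i,2)*v[2];
    Z[i] = verts(i,0)*w[0] + verts(i,1)*w[1] + verts(i,2)*w[2];
    cx += X[i]; cy += Y[i]; cz += Z[i];
  }
  cx /= n; cy /= n; cz /= n;
  double rad = 0;
  for (int i = 0; i < n; ++i) {
    X[i] -= cx; Y[i] -= cy; Z[i] -= cz;
    rad = std::max(rad, std::sqrt(X[i]*X[i] + Y[i]*Y[i] + Z[i]*Z[i]));
  }
  if (rad <= 0) return List::create(_["ok"] = false, _["msg"] = "degenerate polygon");
  for (int i = 0; i < n; ++i) { X[i] /= rad; Y[i] /= rad; Z[i] /= rad; }

  struct Hit { double si, tj, zi, zj; int ei, ej, sign; };
  std::vector<Hit> hits;
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double ax1 = X[i2] - X[i], ay1 = Y[i2] - Y[i];
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue;  // adjacent via wraparound
      int j2 = (j + 1) % n;
      double bx = X[j2] - X[j], by = Y[j2] - Y[j];
      double den = ax1 * by - ay1 * bx;
      double la = std::sqrt(ax1*ax1 + ay1*ay1), lb = std::sqrt(bx*bx + by*by);
      double rx = X[j] - X[i], ry = Y[j] - Y[i];
      // quick reject
      double s_num = rx * by - ry * bx, t_num = rx * ay1 - ry * ax1;
      if (std::abs(den) <= tol * la * lb) {
        // parallel in projection: degenerate only if they actually overlap
        double cross_r = rx * ay1 - ry * ax1;
        if (std::abs(cross_r) <= tol * la * std::sqrt(rx*rx + ry*ry + 1e-300)) {
          // collinear overlap possible -> flag degenerate
          double t0 = (rx * ax1 + ry * ay1) / (la * la);
          double t1 = t0 + (bx * ax1 + by * ay1) / (la * la);
          if (std::max(std::min(t0, t1), 0.0) <= std::min(std::max(t0, t1), 1.0) + tol)
            return List::create(_["ok"] = false,
                                _["msg"] = "parallel overlapping segments " +
                                           std::to_string(i) + "," + std::to_string(j));
        }
        continue;
      }
      double s = s_num / den, t = t_num / den;
      if (s <= -tol || s >= 1 + tol || t <= -tol || t >= 1 + tol) continue;
      if (s < tol || s > 1 - tol || t < tol || t > 1 - tol)
        return List::create(_["ok"] = false,
                            _["msg"] = "crossing at segment endpoint " +
                                       std::to_string(i) + "," + std::to_string(j));
      double zi = Z[i] + s * (Z[i2] - Z[i]);
      double zj = Z[j] + t * (Z[j2] - Z[j]);
      if (std::abs(zi - zj) <= tol)
        return List::create(_["ok"] = false,
                            _["msg"] = "tangential crossing " + std::to_string(i) +
                                       "," + std::to_string(j));
      int sgn;
      if (zi > zj) sgn = (den > 0) ? 1 : -1;   // edge i over: sign(det[d_over, d_under])
      else sgn = (den > 0) ? -1 : 1;           // det[d_j, d_i] = -det[d_i, d_j]
      hits.push_back({s, t, zi, zj, i, j, sgn});
    }
  }
  int c = (int)hits.size();
  // traversal order of the 2c passages
  struct Ev { double pos; int cross, over; };
  std::vector<Ev> evs;
  evs.reserve(2 * c);
  for (int k = 0; k < c; ++k) {
    evs.push_back({hits[k].ei + hits[k].si, k, hits[k].zi > hits[k].zj ? 1 : 0});
    evs.push_back({hits[k].ej + hits[k].tj, k, hits[k].zj > hits[k].zi ? 1 : 0});
  }
  std::sort(evs.begin(), evs.end(), [](const Ev &a, const Ev &b) { return a.pos < b.pos; });
  for (size_t k = 1; k < evs.size(); ++k)
    if (evs[k].pos - evs[k - 1].pos <= tol)
      return List::create(_["ok"] = false, _["msg"] = "coincident passages along an edge");
  IntegerMatrix code(2, 2 * c);
  for (int k = 0; k < 2 * c; ++k) {
    code(0, k) = evs[k].cross + 1;
    code(1, k) = evs[k].over;
  }
  IntegerVector sg(c);
  for (int k = 0; k < c; ++k) sg[k] = hits[k].sign;
  return List::create(_["ok"] = true, _["comps"] = List::create(code),
                      _["sign"] = sg, _["freeloops"] = 0);
}

// ----------------------------------------------------------------------------
// full classification fast path: polygon -> polynomial string + crossing bound
// (tries the supplied view directions in order until one is generic)
// ----------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_polygon_poly")]]
List cpp_polygon_poly(NumericMatrix verts, NumericMatrix dirs, double tol = 1e-9,
                      int r3_budget = 1000, double max_nodes = 2e5,
                      int simplify_above = 12) {
  std::string lastmsg = "no view direction supplied";
  // phase A: among the first generic views, keep the one whose R1/R2-reduced
  // diagram is smallest (projections are cheap; a lucky view can halve the
  // downstream skein work).  A view reducing to <= 20 crossings is accepted
  // immediately.
  Diag best;
  int bestc = 1 << 30, best_at = -1, generic_seen = 0;
  std::vector<int> spare;   // views not consumed by phase A (ladder fallbacks)
  {
    int a = 0;
    for (; a < dirs.nrow(); ++a) {
      if (generic_seen >= 2) break;
      NumericVector dir = dirs(a, _);
      List pr = cpp_project(verts, dir, tol);
      if (!as<bool>(pr["ok"])) { lastmsg = as<std::string>(pr["msg"]); continue; }
      Diag d = from_R(pr);
      reduce_R1R2(d);
      ++generic_seen;
      int c = n_crossings(d);
      if (c < bestc) { bestc = c; best = d; best_at = a; }
      if (c <= 30) { ++a; break; }
    }
    for (; a < dirs.nrow(); ++a) spare.push_back(a);
  }
  if (best_at < 0)
    return List::create(_["ok"] = false, _["msg"] = lastmsg);
  // phase B: escalation ladder on the chosen diagram; on failure fall back to
  // at most two of the remaining views
  auto attempt = [&](Diag d, int att_idx) -> List {
    if (n_crossings(d) > simplify_above)
      d = simplify_search(std::move(d), r3_budget, simplify_above);
    for (int stage = 0; stage < 2; ++stage) {
      HomflyCtx ctx;
      ctx.max_nodes = stage == 0 ? std::min((long long)max_nodes, (long long)3e4)
                                 : (long long)max_nodes;
      try {
        Poly p = homfly_rec(d, ctx);
        return List::create(_["ok"] = true, _["poly"] = poly_string(p),
                            _["bound"] = n_crossings(d), _["attempt"] = att_idx + 1);
      } catch (std::exception &ex) {
        lastmsg = ex.what();
        if (stage == 0) d = simplify_search(std::move(d), 8 * r3_budget,
                                            simplify_above);
      }
    }
    return List::create(_["ok"] = false, _["msg"] = lastmsg);
  };
  List r = attempt(best, best_at);
  if (as<bool>(r["ok"])) return r;
  int fallbacks = 0;
  for (int a : spare) {
    if (fallbacks >= 4) break;
    NumericVector dir = dirs(a, _);
    List pr = cpp_project(verts, dir, tol);
    if (!as<bool>(pr["ok"])) { lastmsg = as<std::string>(pr["msg"]); continue; }
    Diag d = from_R(pr);
    reduce_R1R2(d);
    ++fallbacks;
    r = attempt(std::move(d), a);
    if (as<bool>(r["ok"])) return r;
  }
  return List::create(_["ok"] = false, _["msg"] = lastmsg);
}

// ----------------------------------------------------------------------------
// DT-code realizability: choose a transversal rotation at each crossing so the
// 4-valent map is planar (V - E + F = 2); returns crossing signs of a canonical
// planar embedding (maximal writhe, then lexicographically first)
// ----------------------------------------------------------------------------

// pairs: c x 2 matrix of the two passage positions (1-based, 1..2c) per crossing
// over:  length-2c 0/1 vector, over flag per position
// [[Rcpp::export(name = ".cpp_dt_embed")]]
List cpp_dt_embed(IntegerMatrix pairs, IntegerVector over) {
  int c = pairs.nrow();
  int N = 2 * c;
  std::vector<int> crossing_at(N), other(N);
  for (int k = 0; k < c; ++k) {
    crossing_at[pairs(k, 0) - 1] = k;
    crossing_at[pairs(k, 1) - 1] = k;
    other[pairs(k, 0) - 1] = pairs(k, 1) - 1;
    other[pairs(k, 1) - 1] = pairs(k, 0) - 1;
  }
  // half-edges: edge t runs position t -> t+1 (mod N); half-edge 2t = head at
  // crossing_at[t+1] (in-slot), 2t+1 = tail at crossing_at[t] (out-slot).
  // At crossing k with passages p (first) and q: slots in rotation order are
  //   chi=0 : in_p, in_q, out_p, out_q        (counterclockwise)
  //   chi=1 : in_p, out_q, out_p, in_q
  // Faces from the rotation system; planar iff F == c + 2.
  auto count_faces = [&](const std::vector<int> &chi) {
    // rotation: for each half-edge (incident slot), the next incident slot ccw
    // encode slots: at crossing k: 0=in_p,1=in_q,2=out_p,3=out_q
    // incident half-edges: in_p at passage p is head of edge (p-1 mod N):
    std::vector<int> slot_he(4 * c);
    for (int k = 0; k < c; ++k) {
      int p = std::min(pairs(k, 0), pairs(k, 1)) - 1;
      int q = std::max(pairs(k, 0), pairs(k, 1)) - 1;
      int in_p = 2 * (((p - 1) + N) % N);      // head half-edge of edge p-1
      int out_p = 2 * p + 1;                   // tail half-edge of edge p
      int in_q = 2 * (((q - 1) + N) % N);
      int out_q = 2 * q + 1;
      slot_he[4 * k + 0] = in_p;
      slot_he[4 * k + 2] = out_p;
      if (chi[k] == 0) { slot_he[4 * k + 1] = in_q; slot_he[4 * k + 3] = out_q; }
      else { slot_he[4 * k + 1] = out_q; slot_he[4 * k + 3] = in_q; }
    }
    // next-ccw slot at same vertex, per half-edge
    std::vector<int> nxt(2 * N);
    for (int k = 0; k < c; ++k)
      for (int s = 0; s < 4; ++s)
        nxt[slot_he[4 * k + s]] = slot_he[4 * k + (s + 1) % 4];
    // face permutation: from half-edge h (directed into its vertex), continue
    // along twin'(rot(h)): here faces = orbits of h -> nxt[twin(h)]
    auto twin = [&](int h) { return h ^ 1; };
    std::vector<char> used(2 * N, 0);
    int faces = 0;
    for (int h = 0; h < 2 * N; ++h) {
      if (used[h]) continue;
      ++faces;
      int x = h;
      while (!used[x]) { used[x] = 1; x = nxt[twin(x)]; }
    }
    return faces;
  };
  std::vector<std::vector<int>> planar;
  std::vector<int> chi(c, 0);
  for (long long mask = 0; mask < (1LL << c); ++mask) {
    for (int k = 0; k < c; ++k) chi[k] = (int)((mask >> k) & 1);
    if (count_faces(chi) == c + 2) planar.push_back(chi);
  }
  if (planar.empty())
    return List::create(_["ok"] = false, _["n_embeddings"] = 0);
  // signs: at crossing k with first passage p: rotation chi=0 gives
  // sign = +1 if passage p is the overpass, else -1; chi=1 flips it
  auto signs_of = [&](const std::vector<int> &ch) {
    IntegerVector s(c);
    for (int k = 0; k < c; ++k) {
      int p = std::min(pairs(k, 0), pairs(k, 1)) - 1;
      int base = over[p] ? 1 : -1;
      s[k] = ch[k] == 0 ? base : -base;
    }
    return s;
  };
  int best = 0, bw = -1000000;
  for (size_t i = 0; i < planar.size(); ++i) {
    IntegerVector s = signs_of(planar[i]);
    int wr = std::accumulate(s.begin(), s.end(), 0);
    if (wr > bw) { bw = wr; best = (int)i; }
  }
  return List::create(_["ok"] = true, _["sign"] = signs_of(planar[best]),
                      _["writhe"] = bw, _["n_embeddings"] = (int)planar.size());
}

// fast realizability-only check for census enumeration
// [[Rcpp::export(name = ".cpp_dt_realizable")]]
bool cpp_dt_realizable(IntegerMatrix pairs) {
  int c = pairs.nrow();
  IntegerVector over(2 * c, 1);
  List r = cpp_dt_embed(pairs, over);
  return as<bool>(r["ok"]);
}

// ----------------------------------------------------------------------------
// random equilateral polygon: antipodal edge-vector pairs, random permutation,
// then crankshaft rotations; uses R's RNG so results are seed-reproducible
// ----------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_random_polygon")]]
NumericMatrix cpp_random_polygon(int n, int n_crank) {
  RNGScope scope;
  int half = n / 2;
  std::vector<double> ex(n), ey(n), ez(n);
  for (int i = 0; i < half; ++i) {
    double z = 2.0 * R::unif_rand() - 1.0;
    double th = 2.0 * M_PI * R::unif_rand();
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    ex[i] = r * std::cos(th); ey[i] = r * std::sin(th); ez[i] = z;
    ex[half + i] = -ex[i]; ey[half + i] = -ey[i]; ez[half + i] = -ez[i];
  }
  // Fisher-Yates with R RNG
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(ex[i], ex[j]); std::swap(ey[i], ey[j]); std::swap(ez[i], ez[j]);
  }
  std::vector<double> px(n), py(n), pz(n);
  double x = 0, y = 0, z = 0;
  for (int i = 0; i < n; ++i) {
    px[i] = x; py[i] = y; pz[i] = z;
    x += ex[i]; y += ey[i]; z += ez[i];
  }
  // crankshaft: rotate the arc strictly between two distinct vertices about the
  // chord through them by a uniform angle; preserves closure and edge lengths
  for (int it = 0; it < n_crank; ++it) {
    int i = (int)std::floor(R::unif_rand() * n);
    int j = (int)std::floor(R::unif_rand() * n);
    if (i == j) continue;
    int a = std::min(i, j), b = std::max(i, j);
    double axx = px[b] - px[a], axy = py[b] - py[a], axz = pz[b] - pz[a];
    double an = std::sqrt(axx*axx + axy*axy + axz*axz);
    if (an < 1e-12) continue;
    axx /= an; axy /= an; axz /= an;
    double th = 2.0 * M_PI * R::unif_rand();
    double ct = std::cos(th), st = std::sin(th);
    for (int k = a + 1; k < b; ++k) {
      double vx = px[k] - px[a], vy = py[k] - py[a], vz = pz[k] - pz[a];
      double dot = vx*axx + vy*axy + vz*axz;
      double cxx = axy*vz - axz*vy, cxy = axz*vx - axx*vz, cxz = axx*vy - axy*vx;
      px[a + (k - a)] = px[a] + vx*ct + cxx*st + axx*dot*(1 - ct);
      py[a + (k - a)] = py[a] + vy*ct + cxy*st + axy*dot*(1 - ct);
      pz[a + (k - a)] = pz[a] + vz*ct + cxz*st + axz*dot*(1 - ct);
    }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) { out(i,0) = px[i]; out(i,1) = py[i]; out(i,2) = pz[i]; }
  return out;
}

// ----------------------------------------------------------------------------
// batched uniform-closure classification: build the two-ray closure of an open
// chain for each closure direction and return the HOMFLYPT string of each
// closed polygon.  Ray length: L = span along the direction + 3 * bbox-diameter
// * (1 + hull_margin), which puts both ray tips strictly beyond every vertex in
// the closure direction, hence outside the (scaled) convex hull.
// ----------------------------------------------------------------------------

static void rodrigues(double *d, const double *ax, double th) {
  double ct = std::cos(th), st = std::sin(th);
  double dot = d[0]*ax[0] + d[1]*ax[1] + d[2]*ax[2];
  double cr[3] = {ax[1]*d[2] - ax[2]*d[1], ax[2]*d[0] - ax[0]*d[2], ax[0]*d[1] - ax[1]*d[0]};
  for (int k = 0; k < 3; ++k) d[k] = d[k]*ct + cr[k]*st + ax[k]*dot*(1 - ct);
}

// [[Rcpp::export(name = ".cpp_closure_polys")]]
List cpp_closure_polys(NumericMatrix chain, NumericMatrix cdirs, double hull_margin,
                       NumericMatrix viewdirs, double tol = 1e-9, int r3_budget = 1000,
                       double max_nodes = 2e5, int simplify_above = 12) {
  int n = chain.nrow(), nd = cdirs.nrow();
  StringVector polys(nd);
  LogicalVector ok(nd);
  IntegerVector bound(nd), attempts(nd), perturbed(nd);
  // bounding-box diameter
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = hi[k] = chain(0, k); }
  for (int i = 1; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], chain(i, k));
      hi[k] = std::max(hi[k], chain(i, k));
    }
  double diam = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) + (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diam <= 0) diam = 1;
  NumericMatrix closed(n + 2, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) closed(i, k) = chain(i, k);
  for (int di = 0; di < nd; ++di) {
    double d[3] = {cdirs(di, 0), cdirs(di, 1), cdirs(di, 2)};
    double nrm = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
    for (double &x : d) x /= nrm;
    // fixed perturbation axis orthogonal to d
    int axmin = 0;
    for (int k = 1; k < 3; ++k) if (std::abs(d[k]) < std::abs(d[axmin])) axmin = k;
    double e[3] = {0, 0, 0};
    e[axmin] = 1;
    double axp[3] = {e[1]*d[2] - e[2]*d[1], e[2]*d[0] - e[0]*d[2], e[0]*d[1] - e[1]*d[0]};
    double na = std::sqrt(axp[0]*axp[0] + axp[1]*axp[1] + axp[2]*axp[2]);
    for (double &x : axp) x /= na;
    int pert = 0;
    for (; pert < 8; ++pert) {
      if (pert > 0) rodrigues(d, axp, 1e-6 * std::pow(8.0, pert - 1));
      // span along d and ray-through-vertex degeneracy test
      double mx = -1e300;
      for (int i = 0; i < n; ++i)
        mx = std::max(mx, chain(i,0)*d[0] + chain(i,1)*d[1] + chain(i,2)*d[2]);
      double endA = chain(0,0)*d[0] + chain(0,1)*d[1] + chain(0,2)*d[2];
      double endB = chain(n-1,0)*d[0] + chain(n-1,1)*d[1] + chain(n-1,2)*d[2];
      double L = mx - std::min(endA, endB) + 3.0 * diam * (1.0 + hull_margin);
      for (int k = 0; k < 3; ++k) {
        closed(n, k) = chain(n - 1, k) + L * d[k];      // tip beyond endpoint B
        closed(n + 1, k) = chain(0, k) + L * d[k];      // tip beyond endpoint A
      }
      // the rays and the tip-joining segment must stay clear of the chain
      // (a true 3-D intersection has no generic projection at all)
      auto segdist = [](const double *p1, const double *p2,
                        const double *q1, const double *q2) {
        double u[3], v[3], w[3];
        for (int k = 0; k < 3; ++k) {
          u[k] = p2[k] - p1[k];
          v[k] = q2[k] - q1[k];
          w[k] = p1[k] - q1[k];
        }
        double a = u[0]*u[0]+u[1]*u[1]+u[2]*u[2];
        double b = u[0]*v[0]+u[1]*v[1]+u[2]*v[2];
        double cc = v[0]*v[0]+v[1]*v[1]+v[2]*v[2];
        double dd = u[0]*w[0]+u[1]*w[1]+u[2]*w[2];
        double e2 = v[0]*w[0]+v[1]*w[1]+v[2]*w[2];
        double den = a*cc - b*b;
        double s = 0, t = 0;
        if (den > 1e-14 * a * cc + 1e-300) {
          s = (b*e2 - cc*dd) / den;
          t = (a*e2 - b*dd) / den;
        }
        s = std::max(0.0, std::min(1.0, s));
        // refine t for clamped s, then s for clamped t
        t = cc > 0 ? (e2 + s*b) / cc : 0;
        t = std::max(0.0, std::min(1.0, t));
        s = a > 0 ? (t*b - dd) / a : 0;
        s = std::max(0.0, std::min(1.0, s));
        double dx = w[0] + s*u[0] - t*v[0];
        double dy = w[1] + s*u[1] - t*v[1];
        double dz = w[2] + s*u[2] - t*v[2];
        return std::sqrt(dx*dx + dy*dy + dz*dz);
      };
      bool clear = true;
      double segs[3][6];
      for (int k = 0; k < 3; ++k) {
        segs[0][k] = chain(n-1, k);  segs[0][3+k] = closed(n, k);      // ray at B
        segs[1][k] = chain(0, k);    segs[1][3+k] = closed(n+1, k);    // ray at A
        segs[2][k] = closed(n, k);   segs[2][3+k] = closed(n+1, k);    // tip joiner
      }
      for (int e = 0; e < n - 1 && clear; ++e) {
        double q1[3] = {chain(e,0), chain(e,1), chain(e,2)};
        double q2[3] = {chain(e+1,0), chain(e+1,1), chain(e+1,2)};
        for (int which = 0; which < 3 && clear; ++which) {
          // skip the chain edge sharing the ray's base vertex
          if (which == 0 && e == n - 2) continue;
          if (which == 1 && e == 0) continue;
          if (segdist(segs[which], segs[which] + 3, q1, q2) < 1e-9 * diam)
            clear = false;
        }
      }
      if (clear) break;
    }
    perturbed[di] = pert;
    List r = cpp_polygon_poly(closed, viewdirs, tol, r3_budget, max_nodes, simplify_above);
    if (as<bool>(r["ok"])) {
      ok[di] = true;
      polys[di] = as<String>(r["poly"]);
      bound[di] = as<int>(r["bound"]);
      attempts[di] = as<int>(r["attempt"]);
    } else {
      ok[di] = false;
      polys[di] = NA_STRING;
      bound[di] = NA_INTEGER;
      attempts[di] = viewdirs.nrow();
    }
  }
  return List::create(_["ok"] = ok, _["poly"] = polys, _["bound"] = bound,
                      _["attempts"] = attempts, _["perturbed"] = perturbed);
}
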