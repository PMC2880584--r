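// Fraction-free Buchberger engine with arbitrary-precision integer
// coefficients.
//
// Lexicographic Groebner bases of steady-state systems suffer large
// intermediate integer coefficients even when inputs are small; IEEE
// doubles hold exact integers only up to 2^53, so the exact kernel lives
// here. Coefficients are sign + magnitude in base 1e9 limbs; polynomials
// are term lists sorted in decreasing lexicographic order. The algorithm
// mirrors the package's documented strategy: pseudo-reduction (scale by
// leading coefficients instead of dividing), content stripping after every
// step, Buchberger's coprimality and chain criteria, normal pair
// selection, then minimalization and full inter-reduction; results are
// primitive with positive leading coefficients and sorted by increasing
// leading monomial.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const uint32_t BASE = 1000000000u;

struct Big {
  int sign = 0;                 // -1, 0, +1
  std::vector<uint32_t> d;      // little-endian base-1e9 limbs

  void trim() {
    while (!d.empty() && d.back() == 0) d.pop_back();
    if (d.empty()) sign = 0;
  }
  bool isZero() const { return sign == 0; }
};

static int cmpMag(const Big& a, const Big& b) {
  if (a.d.size() != b.d.size()) return a.d.size() < b.d.size() ? -1 : 1;
  for (size_t i = a.d.size(); i-- > 0;) {
    if (a.d[i] != b.d[i]) return a.d[i] < b.d[i] ? -1 : 1;
  }
  return 0;
}

static std::vector<uint32_t> addMag(const std::vector<uint32_t>& a,
                                    const std::vector<uint32_t>& b) {
  std::vector<uint32_t> r;
  r.reserve(std::max(a.size(), b.size()) + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < std::max(a.size(), b.size()) || carry; ++i) {
    uint64_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    r.push_back((uint32_t)(s % BASE));
    carry = s / BASE;
  }
  return r;
}

// a - b, requires |a| >= |b|
static std::vector<uint32_t> subMag(const std::vector<uint32_t>& a,
                                    const std::vector<uint32_t>& b) {
  std::vector<uint32_t> r = a;
  int64_t borrow = 0;
  for (size_t i = 0; i < r.size(); ++i) {
    int64_t s = (int64_t)r[i] - borrow - (i < b.size() ? b[i] : 0);
    if (s < 0) { s += BASE; borrow = 1; } else borrow = 0;
    r[i] = (uint32_t)s;
  }
  while (!r.empty() && r.back() == 0) r.pop_back();
  return r;
}

static Big add(const Big& a, const Big& b) {
  if (a.isZero()) return b;
  if (b.isZero()) return a;
  Big r;
  if (a.sign == b.sign) {
    r.sign = a.sign;
    r.d = addMag(a.d, b.d);
  } else {
    int c = cmpMag(a, b);
    if (c == 0) return r; // zero
    if (c > 0) { r.sign = a.sign; r.d = subMag(a.d, b.d); }
    else { r.sign = b.sign; r.d = subMag(b.d, a.d); }
  }
  r.trim();
  return r;
}

static Big mul(const Big& a, const Big& b) {
  Big r;
  if (a.isZero() || b.isZero()) return r;
  r.sign = a.sign * b.sign;
  r.d.assign(a.d.size() + b.d.size(), 0);
  for (size_t i = 0; i < a.d.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.d.size() || carry; ++j) {
      uint64_t cur = r.d[i + j] + carry;
      if (j < b.d.size()) cur += (uint64_t)a.d[i] * b.d[j];
      r.d[i + j] = (uint32_t)(cur % BASE);
      carry = cur / BASE;
    }
  }
  r.trim();
  return r;
}

// magnitude division by a single limb
static std::vector<uint32_t> divMagSmall(const std::vector<uint32_t>& a,
                                         uint32_t b, uint32_t* rem) {
  std::vector<uint32_t> q(a.size());
  uint64_t r = 0;
  for (size_t i = a.size(); i-- > 0;) {
    uint64_t cur = r * BASE + a[i];
    q[i] = (uint32_t)(cur / b);
    r = cur % b;
  }
  while (!q.empty() && q.back() == 0) q.pop_back();
  if (rem) *rem = (uint32_t)r;
  return q;
}

// Knuth Algorithm D on magnitudes: a = q*b + r, 0 <= r < b
static void divModMag(const std::vector<uint32_t>& a,
                      const std::vector<uint32_t>& b,
                      std::vector<uint32_t>& q, std::vector<uint32_t>& r) {
  q.clear(); r.clear();
  if (b.empty()) stop("division by zero");
  if (b.size() == 1) {
    uint32_t rr;
    q = divMagSmall(a, b[0], &rr);
    if (rr) r.push_back(rr);
    return;
  }
  Big A; A.sign = 1; A.d = a; A.trim();
  Big B; B.sign = 1; B.d = b;
  if (A.isZero() || cmpMag(A, B) < 0) { r = A.d; return; }
  // normalize so the divisor's top limb is >= BASE/2
  uint32_t dnorm = (uint32_t)(((uint64_t)BASE) / (b.back() + 1ull));
  if (dnorm == 0) dnorm = 1;
  Big D; D.sign = 1; D.d.push_back(dnorm);
  std::vector<uint32_t> u = mul(A, D).d;
  std::vector<uint32_t> v = mul(B, D).d;
  size_t n = v.size(), m = u.size() - n;
  u.push_back(0);
  q.assign(m + 1, 0);
  for (size_t j = m + 1; j-- > 0;) {
    uint64_t top = (uint64_t)u[j + n] * BASE + u[j + n - 1];
    uint64_t qhat = top / v[n - 1];
    uint64_t rhat = top % v[n - 1];
    while (qhat >= BASE ||
           (n >= 2 && qhat * v[n - 2] > rhat * BASE + u[j + n - 2])) {
      --qhat; rhat += v[n - 1];
      if (rhat >= BASE) break;
    }
    // multiply and subtract u[j..j+n] -= qhat * v
    int64_t borrow = 0; uint64_t carry = 0;
    for (size_t i = 0; i < n; ++i) {
      uint64_t p = qhat * v[i] + carry;
      carry = p / BASE;
      int64_t t = (int64_t)u[i + j] - (int64_t)(p % BASE) - borrow;
      if (t < 0) { t += BASE; borrow = 1; } else borrow = 0;
      u[i + j] = (uint32_t)t;
    }
    int64_t t = (int64_t)u[j + n] - (int64_t)carry - borrow;
    if (t < 0) {
      // qhat was one too large: add back
      t += BASE;
      --qhat;
      uint64_t c2 = 0;
      for (size_t i = 0; i < n; ++i) {
        uint64_t s = (uint64_t)u[i + j] + v[i] + c2;
        u[i + j] = (uint32_t)(s % BASE);
        c2 = s / BASE;
      }
      t += (int64_t)c2;
      if (t >= (int64_t)BASE) t -= BASE;
    }
    u[j + n] = (uint32_t)t;
    q[j] = (uint32_t)qhat;
  }
  while (!q.empty() && q.back() == 0) q.pop_back();
  // denormalize remainder
  std::vector<uint32_t> rr(u.begin(), u.begin() + n);
  while (!rr.empty() && rr.back() == 0) rr.pop_back();
  uint32_t dummy;
  r = divMagSmall(rr, dnorm, &dummy);
}

static Big gcdBig(Big a, Big b) {
  a.sign = a.isZero() ? 0 : 1;
  b.sign = b.isZero() ? 0 : 1;
  while (!b.isZero()) {
    std::vector<uint32_t> q, r;
    divModMag(a.d, b.d, q, r);
    a.d = b.d;
    b.d = r;
    b.trim(); a.trim();
    a.sign = a.d.empty() ? 0 : 1;
    b.sign = b.d.empty() ? 0 : 1;
  }
  return a;
}

// exact division (caller guarantees divisibility)
static Big divExact(const Big& a, const Big& b) {
  Big r;
  if (a.isZero()) return r;
  std::vector<uint32_t> q, rem;
  divModMag(a.d, b.d, q, rem);
  r.d = q;
  r.sign = a.sign * b.sign;
  r.trim();
  return r;
}

static bool isOneMag(const Big& a) { return a.d.size() == 1 && a.d[0] == 1; }

static Big fromString(const std::string& s) {
  Big r;
  size_t start = 0;
  int sign = 1;
  if (!s.empty() && (s[0] == '-' || s[0] == '+')) {
    if (s[0] == '-') sign = -1;
    start = 1;
  }
  for (size_t end = s.size(); end > start;) {
    size_t chunk = std::min<size_t>(9, end - start);
    uint32_t limb = 0;
    for (size_t i = end - chunk; i < end; ++i) {
      if (s[i] < '0' || s[i] > '9') stop("invalid integer string");
      limb = limb * 10u + (uint32_t)(s[i] - '0');
    }
    r.d.push_back(limb);
    end -= chunk;
  }
  r.sign = sign;
  r.trim();
  return r;
}

static std::string toString(const Big& a) {
  if (a.isZero()) return "0";
  std::string s = a.sign < 0 ? "-" : "";
  char buf[16];
  snprintf(buf, sizeof(buf), "%u", a.d.back());
  s += buf;
  for (size_t i = a.d.size() - 1; i-- > 0;) {
    snprintf(buf, sizeof(buf), "%09u", a.d[i]);
    s += buf;
  }
  return s;
}

static double toDouble(const Big& a) {
  double v = 0;
  for (size_t i = a.d.size(); i-- > 0;) v = v * BASE + a.d[i];
  return a.sign < 0 ? -v : v;
}

// ---------------------------------------------------------------------------

typedef std::vector<int> Expo;

struct Poly {
  std::vector<Big> c;
  std::vector<Expo> e; // decreasing lex order
  bool isZero() const { return c.empty(); }
};

static int lexCmp(const Expo& a, const Expo& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  }
  return 0;
}

static bool divides(const Expo& a, const Expo& b) {
  for (size_t i = 0; i < a.size(); ++i)
    if (a[i] > b[i]) return false;
  return true;
}

// r = sa*p + sb*x^m*g, both inputs sorted: merge
static Poly combine(const Poly& p, const Big& sa, const Poly& g,
                    const Big& sb, const Expo& m) {
  Poly r;
  r.c.reserve(p.c.size() + g.c.size());
  r.e.reserve(p.c.size() + g.c.size());
  size_t i = 0, j = 0;
  Expo ge(m.size());
  while (i < p.c.size() || j < g.c.size()) {
    int cmp;
    if (i >= p.c.size()) cmp = -1;
    else if (j >= g.c.size()) cmp = 1;
    else {
      for (size_t t = 0; t < m.size(); ++t) ge[t] = g.e[j][t] + m[t];
      cmp = lexCmp(p.e[i], ge);
    }
    if (cmp > 0) {
      Big v = mul(p.c[i], sa);
      if (!v.isZero()) { r.c.push_back(v); r.e.push_back(p.e[i]); }
      ++i;
    } else if (cmp < 0) {
      for (size_t t = 0; t < m.size(); ++t) ge[t] = g.e[j][t] + m[t];
      Big v = mul(g.c[j], sb);
      if (!v.isZero()) { r.c.push_back(v); r.e.push_back(ge); }
      ++j;
    } else {
      Big v = add(mul(p.c[i], sa), mul(g.c[j], sb));
      if (!v.isZero()) { r.c.push_back(v); r.e.push_back(p.e[i]); }
      ++i; ++j;
    }
  }
  return r;
}

static void makePrimitive(Poly& p) {
  if (p.isZero()) return;
  Big g = p.c[0];
  g.sign = 1;
  for (size_t i = 1; i < p.c.size() && !isOneMag(g); ++i) g = gcdBig(g, p.c[i]);
  bool flip = p.c[0].sign < 0;
  if (isOneMag(g) && !flip) return;
  for (size_t i = 0; i < p.c.size(); ++i) {
    if (!isOneMag(g)) p.c[i] = divExact(p.c[i], g);
    if (flip) p.c[i].sign = -p.c[i].sign;
  }
}

// full normal form of p modulo G (fraction-free with content stripping)
static Poly reduceFull(Poly p, const std::vector<Poly>& G, bool full = true) {
  Poly rem;
  while (!p.isZero()) {
    const Expo& lp = p.e[0];
    int hit = -1;
    for (size_t gi = 0; gi < G.size(); ++gi) {
      if (divides(G[gi].e[0], lp)) { hit = (int)gi; break; }
    }
    if (hit >= 0) {
      const Poly& g = G[hit];
      Big d = gcdBig(p.c[0], g.c[0]);
      Big a = divExact(g.c[0], d); a.sign = 1;
      Big b = divExact(p.c[0], d);
      if (g.c[0].sign < 0) b.sign = -b.sign;
      Expo m(lp.size());
      for (size_t t = 0; t < lp.size(); ++t) m[t] = lp[t] - g.e[0][t];
      if (!isOneMag(a)) {
        for (size_t i = 0; i < rem.c.size(); ++i) rem.c[i] = mul(rem.c[i], a);
      }
      b.sign = -b.sign;
      p = combine(p, a, g, b, m);
      // joint content strip over remainder + p
      if (!p.isZero() || !rem.isZero()) {
        Big cg; cg.sign = 0;
        for (size_t i = 0; i < rem.c.size() && !isOneMag(cg); ++i)
          cg = cg.isZero() ? rem.c[i] : gcdBig(cg, rem.c[i]);
        for (size_t i = 0; i < p.c.size() && !isOneMag(cg); ++i)
          cg = cg.isZero() ? p.c[i] : gcdBig(cg, p.c[i]);
        cg.sign = 1;
        if (!cg.isZero() && !isOneMag(cg)) {
          for (size_t i = 0; i < rem.c.size(); ++i)
            rem.c[i] = divExact(rem.c[i], cg);
          for (size_t i = 0; i < p.c.size(); ++i)
            p.c[i] = divExact(p.c[i], cg);
        }
      }
    } else if (full) {
      rem.c.push_back(p.c[0]);
      rem.e.push_back(p.e[0]);
      p.c.erase(p.c.begin());
      p.e.erase(p.e.begin());
    } else break;
  }
  if (full) {
    makePrimitive(rem);
    return rem;
  }
  // partial reduction: remainder terms stay in front of p
  for (size_t i = 0; i < p.c.size(); ++i) {
    rem.c.push_back(p.c[i]);
    rem.e.push_back(p.e[i]);
  }
  makePrimitive(rem);
  return rem;
}

static Poly spoly(const Poly& f, const Poly& g) {
  const Expo& lf = f.e[0];
  const Expo& lg = g.e[0];
  Expo l(lf.size()), mf(lf.size()), mg(lf.size());
  for (size_t t = 0; t < lf.size(); ++t) {
    l[t] = std::max(lf[t], lg[t]);
    mf[t] = l[t] - lf[t];
    mg[t] = l[t] - lg[t];
  }
  Big d = gcdBig(f.c[0], g.c[0]);
  Big a = divExact(g.c[0], d);
  Big b = divExact(f.c[0], d);
  b.sign = -b.sign;
  // a * x^mf * f + (-b) * x^mg * g ; reuse combine with p = x^mf * f
  Poly fs = f;
  for (size_t i = 0; i < fs.e.size(); ++i)
    for (size_t t = 0; t < mf.size(); ++t) fs.e[i][t] += mf[t];
  Poly s = combine(fs, a, g, b, mg);
  makePrimitive(s);
  return s;
}

struct Pair { int i, j; Expo l; int deg; };

static std::vector<Poly> interReduce(std::vector<Poly> G) {
  // minimalize
  std::vector<bool> keep(G.size(), true);
  for (size_t i = 0; i < G.size(); ++i) {
    for (size_t j = 0; j < G.size(); ++j) {
      if (i == j || !keep[j]) continue;
      if (keep[i] && divides(G[j].e[0], G[i].e[0])) { keep[i] = false; break; }
    }
  }
  std::vector<Poly> H;
  for (size_t i = 0; i < G.size(); ++i)
    if (keep[i]) H.push_back(G[i]);
  // full inter-reduction
  bool changed = true;
  while (changed) {
    changed = false;
    for (size_t i = 0; i < H.size(); ++i) {
      std::vector<Poly> rest;
      for (size_t j = 0; j < H.size(); ++j)
        if (j != i) rest.push_back(H[j]);
      Poly r = reduceFull(H[i], rest);
      bool same = r.c.size() == H[i].c.size();
      if (same) {
        for (size_t t = 0; t < r.c.size() && same; ++t) {
          if (lexCmp(r.e[t], H[i].e[t]) != 0 ||
              cmpMag(r.c[t], H[i].c[t]) != 0 ||
              r.c[t].sign != H[i].c[t].sign) same = false;
        }
      }
      if (!same) {
        changed = true;
        if (r.isZero()) {
          H.erase(H.begin() + i);
        } else {
          H[i] = r;
        }
        break;
      }
    }
  }
  // sort by increasing leading monomial
  std::sort(H.begin(), H.end(), [](const Poly& a, const Poly& b) {
    return lexCmp(a.e[0], b.e[0]) < 0;
  });
  return H;
}

static std::vector<Poly> buchberger(std::vector<Poly> G, int max_pairs) {
  size_t nv = G[0].e[0].size();
  std::vector<Pair> pairs;
  std::vector<std::vector<bool>> done(G.size(),
                                      std::vector<bool>(G.size(), false));
  auto addPairs = [&](int t) {
    for (int i = 0; i < t; ++i) {
      Pair pr; pr.i = i; pr.j = t; pr.l.resize(nv); pr.deg = 0;
      for (size_t v = 0; v < nv; ++v) {
        pr.l[v] = std::max(G[i].e[0][v], G[t].e[0][v]);
        pr.deg += pr.l[v];
      }
      pairs.push_back(pr);
    }
  };
  for (size_t t = 1; t < G.size(); ++t) addPairs((int)t);
  int processed = 0;
  while (!pairs.empty()) {
    if (processed > max_pairs)
      stop("Groebner computation exceeded the pair budget; substitute "
           "numeric parameters or reduce the system");
    // normal strategy: smallest lcm (total degree, then lex-smallest)
    size_t best = 0;
    for (size_t t = 1; t < pairs.size(); ++t) {
      if (pairs[t].deg < pairs[best].deg ||
          (pairs[t].deg == pairs[best].deg &&
           lexCmp(pairs[t].l, pairs[best].l) < 0)) best = t;
    }
    Pair pr = pairs[best];
    pairs.erase(pairs.begin() + best);
    done[pr.i][pr.j] = done[pr.j][pr.i] = true;
    ++processed;
    // coprimality criterion
    bool coprime = true;
    for (size_t v = 0; v < nv && coprime; ++v)
      if (G[pr.i].e[0][v] > 0 && G[pr.j].e[0][v] > 0) coprime = false;
    if (coprime) continue;
    // chain criterion
    bool skip = false;
    for (size_t t = 0; t < G.size() && !skip; ++t) {
      if ((int)t == pr.i || (int)t == pr.j) continue;
      if (divides(G[t].e[0], pr.l) && done[pr.i][t] && done[pr.j][t])
        skip = true;
    }
    if (skip) continue;
    Poly s = reduceFull(spoly(G[pr.i], G[pr.j]), G);
    if (s.isZero()) continue;
    bool unit = true;
    for (size_t v = 0; v < nv; ++v)
      if (s.e[0][v] != 0) { unit = false; break; }
    if (unit) {
      Poly one;
      Big b1; b1.sign = 1; b1.d.push_back(1);
      one.c.push_back(b1);
      one.e.push_back(Expo(nv, 0));
      return std::vector<Poly>(1, one);
    }
    G.push_back(s);
    for (auto& row : done) row.push_back(false);
    done.push_back(std::vector<bool>(G.size(), false));
    addPairs((int)G.size() - 1);
    Rcpp::checkUserInterrupt();
  }
  return interReduce(G);
}

// --------------------------------------------------------------------------

static Poly polyFromR(const CharacterVector& coef, const IntegerMatrix& expo) {
  Poly p;
  for (int i = 0; i < coef.size(); ++i) {
    Big b = fromString(as<std::string>(coef[i]));
    if (b.isZero()) continue;
    p.c.push_back(b);
    Expo e(expo.ncol());
    for (int j = 0; j < expo.ncol(); ++j) e[j] = expo(i, j);
    p.e.push_back(e);
  }
  return p;
}

static List polyToR(const Poly& p, int nv) {
  CharacterVector cs(p.c.size());
  NumericVector cn(p.c.size());
  IntegerMatrix ex(p.c.size(), nv);
  for (size_t i = 0; i < p.c.size(); ++i) {
    cs[i] = toString(p.c[i]);
    cn[i] = toDouble(p.c[i]);
    for (int j = 0; j < nv; ++j) ex(i, j) = p.e[i][j];
  }
  return List::create(Named("coef_str") = cs, Named("coef") = cn,
                      Named("expo") = ex);
}

// [[Rcpp::export]]
List cpp_groebner(List coefs, List expos, int max_pairs) {
  std::vector<Poly> G;
  int nv = -1;
  for (int i = 0; i < coefs.size(); ++i) {
    IntegerMatrix ex = expos[i];
    nv = ex.ncol();
    Poly p = polyFromR(coefs[i], ex);
    if (!p.isZero()) {
      makePrimitive(p);
      G.push_back(p);
    }
  }
  if (G.empty()) stop("all input polynomials are zero");
  std::vector<Poly> B = buchberger(G, max_pairs);
  List out(B.size());
  for (size_t i = 0; i < B.size(); ++i) out[i] = polyToR(B[i], nv);
  return out;
}

// [[Rcpp::export]]
List cpp_reduce(CharacterVector pcoef, IntegerMatrix pexpo, List bcoefs,
                List bexpos) {
  Poly p = polyFromR(pcoef, pexpo);
  std::vector<Poly> G;
  for (int i = 0; i < bcoefs.size(); ++i) {
    Poly g = polyFromR(bcoefs[i], bexpos[i]);
    if (!g.isZero()) G.push_back(g);
  }
  int nv = pexpo.ncol();
  if (p.isZero()) return polyToR(p, nv);
  makePrimitive(p);
  return polyToR(reduceFull(p, G), nv);
}

// [[Rcpp::export]]
List cpp_bigint_selftest(CharacterVector a, CharacterVector b) {
  // exercised by the test suite: returns a+b, a*b, gcd(a,b), a %/% b, a %% b
  Big A = fromString(as<std::string>(a[0]));
  Big B = fromString(as<std::string>(b[0]));
  std::vector<uint32_t> q, r;
  CharacterVector out(5);
  out[0] = toString(add(A, B));
  out[1] = toString(mul(A, B));
  out[2] = toString(gcdBig(A, B));
  if (!B.isZero()) {
    divModMag(A.d, B.d, q, r);
    Big Q; Q.d = q; Q.sign = q.empty() ? 0 : 1; Q.trim();
    Big R; R.d = r; R.sign = r.empty() ? 0 : 1; R.trim();
    out[3] = toString(Q);
    out[4] = toString(R);
  } else {
    out[3] = NA_STRING;
    out[4] = NA_STRING;
  }
  return List::create(Named("res") = out);
}
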