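// Exact arbitrary-precision non-negative integer arithmetic on decimal strings.
//
// Criteria encodings reach ~28 decimal digits and dual-diagnosis composites are
// products of two such values (~56 digits), far beyond the 2^53 exact-integer
// range of a double, so every arithmetic step here is exact. Numbers are held
// as little-endian limb vectors in base 1e9.

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

typedef std::vector<uint32_t> limbs;
static const uint64_t BASE = 1000000000ULL;

static limbs parse_big(const std::string& s) {
  if (s.empty()) stop("empty string is not a number");
  for (char c : s)
    if (c < '0' || c > '9')
      stop("not a non-negative integer: '%s'", s.c_str());
  limbs out;
  int n = (int)s.size();
  for (int end = n; end > 0; end -= 9) {
    int start = end - 9 < 0 ? 0 : end - 9;
    uint32_t limb = 0;
    for (int k = start; k < end; ++k) limb = limb * 10u + (uint32_t)(s[k] - '0');
    out.push_back(limb);
  }
  while (out.size() > 1 && out.back() == 0) out.pop_back();
  return out;
}

static std::string format_big(const limbs& a) {
  std::string s = std::to_string(a.back());
  char buf[16];
  for (int i = (int)a.size() - 2; i >= 0; --i) {
    snprintf(buf, sizeof(buf), "%09u", a[i]);
    s += buf;
  }
  return s;
}

static bool is_zero(const limbs& a) { return a.size() == 1 && a[0] == 0; }

static int cmp_big(const limbs& a, const limbs& b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (int i = (int)a.size() - 1; i >= 0; --i)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

static limbs mul_big(const limbs& a, const limbs& b) {
  if (is_zero(a) || is_zero(b)) return limbs(1, 0);
  std::vector<uint64_t> acc(a.size() + b.size(), 0);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      uint64_t cur = acc[i + j] + (uint64_t)a[i] * b[j] + carry;
      acc[i + j] = cur % BASE;
      carry = cur / BASE;
    }
    size_t k = i + b.size();
    while (carry) {
      uint64_t cur = acc[k] + carry;
      acc[k] = cur % BASE;
      carry = cur / BASE;
      ++k;
    }
  }
  limbs out(acc.begin(), acc.end());
  while (out.size() > 1 && out.back() == 0) out.pop_back();
  return out;
}

static limbs mul_small(const limbs& a, uint32_t m) {
  if (m == 0) return limbs(1, 0);
  limbs out(a.size(), 0);
  uint64_t carry = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t cur = (uint64_t)a[i] * m + carry;
    out[i] = cur % BASE;
    carry = cur / BASE;
  }
  while (carry) {
    out.push_back(carry % BASE);
    carry /= BASE;
  }
  return out;
}

// a - b, requires a >= b
static limbs sub_big(const limbs& a, const limbs& b) {
  limbs out(a);
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t cur = (int64_t)out[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (cur < 0) { cur += BASE; borrow = 1; } else borrow = 0;
    out[i] = (uint32_t)cur;
  }
  while (out.size() > 1 && out.back() == 0) out.pop_back();
  return out;
}

// quotient and remainder of a / m for small m
static limbs divmod_small(const limbs& a, uint32_t m, uint32_t& rem) {
  limbs q(a.size(), 0);
  uint64_t r = 0;
  for (int i = (int)a.size() - 1; i >= 0; --i) {
    uint64_t cur = r * BASE + a[i];
    q[i] = (uint32_t)(cur / m);
    r = cur % m;
  }
  while (q.size() > 1 && q.back() == 0) q.pop_back();
  rem = (uint32_t)r;
  return q;
}

// remainder of a / b by limb-wise long division; quotient limb by binary search
static limbs mod_big(const limbs& a, const limbs& b) {
  if (is_zero(b)) stop("division by zero");
  if (cmp_big(a, b) < 0) return a;
  limbs r(1, 0);
  for (int i = (int)a.size() - 1; i >= 0; --i) {
    // r = r * BASE + a[i]
    if (!is_zero(r)) r.insert(r.begin(), a[i]);
    else r[0] = a[i];
    if (cmp_big(r, b) >= 0) {
      uint32_t lo = 1, hi = (uint32_t)(BASE - 1), q = 1;
      while (lo <= hi) {
        uint32_t mid = lo + (hi - lo) / 2;
        if (cmp_big(mul_small(b, mid), r) <= 0) { q = mid; lo = mid + 1; }
        else hi = mid - 1;
      }
      r = sub_big(r, mul_small(b, q));
    }
  }
  return r;
}

static R_xlen_t recycled_len(R_xlen_t na, R_xlen_t nb) {
  if (na == 0 || nb == 0) return 0;
  return na > nb ? na : nb;
}

//' @noRd
// [[Rcpp::export(name = ".big_mul")]]
CharacterVector big_mul_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = recycled_len(a.size(), b.size());
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    limbs x = parse_big(as<std::string>(a[i % a.size()]));
    limbs y = parse_big(as<std::string>(b[i % b.size()]));
    out[i] = format_big(mul_big(x, y));
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".big_cmp")]]
IntegerVector big_cmp_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = recycled_len(a.size(), b.size());
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = cmp_big(parse_big(as<std::string>(a[i % a.size()])),
                     parse_big(as<std::string>(b[i % b.size()])));
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".big_mod")]]
CharacterVector big_mod_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = recycled_len(a.size(), b.size());
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = format_big(mod_big(parse_big(as<std::string>(a[i % a.size()])),
                                parse_big(as<std::string>(b[i % b.size()]))));
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".big_divisible")]]
LogicalVector big_divisible_cpp(CharacterVector a, CharacterVector b) {
  R_xlen_t n = recycled_len(a.size(), b.size());
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = is_zero(mod_big(parse_big(as<std::string>(a[i % a.size()])),
                             parse_big(as<std::string>(b[i % b.size()]))));
  }
  return out;
}

// product of a vector of small positive integers, as a decimal string
//' @noRd
// [[Rcpp::export(name = ".big_prod")]]
String big_prod_cpp(IntegerVector xs) {
  limbs acc(1, 1);
  for (R_xlen_t i = 0; i < xs.size(); ++i) {
    if (xs[i] == NA_INTEGER || xs[i] <= 0) stop("factors must be positive integers");
    acc = mul_small(acc, (uint32_t)xs[i]);
  }
  return format_big(acc);
}

// trial division of each value over a fixed factor base; returns the exponent
// matrix (values x base) and the residual cofactor left after removing all
// base primes
//' @noRd
// [[Rcpp::export(name = ".big_factor")]]
List big_factor_cpp(CharacterVector values, IntegerVector base) {
  R_xlen_t nv = values.size(), nb = base.size();
  IntegerMatrix expo(nv, nb);
  CharacterVector residue(nv);
  for (R_xlen_t i = 0; i < nv; ++i) {
    limbs v = parse_big(as<std::string>(values[i]));
    for (R_xlen_t j = 0; j < nb; ++j) {
      uint32_t p = (uint32_t)base[j];
      uint32_t rem;
      int e = 0;
      while (!is_zero(v)) {
        limbs q = divmod_small(v, p, rem);
        if (rem != 0) break;
        v = q;
        ++e;
      }
      expo(i, j) = e;
    }
    residue[i] = format_big(v);
  }
  return List::create(_["exponents"] = expo, _["residue"] = residue);
}
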