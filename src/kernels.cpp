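// String-based CI kernels: excitation link tables, same-spin Hamiltonian
// triplets, opposite-spin sigma contraction, S^2 application.
//
// Half-strings (one spin species) are unsigned bit words over n_orb spatial
// orbitals; bit p set means orbital p occupied. All indices 0-based here;
// R wrappers re-base at the surface.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

static inline int popcnt(uint32_t x) { return __builtin_popcount(x); }

// parity of occupied orbitals strictly below bit b
static inline int parity_below(uint32_t s, int b) {
  uint32_t mask = (b == 0) ? 0u : ((1u << b) - 1u);
  return popcnt(s & mask) & 1;
}

typedef std::unordered_map<uint32_t, int> StrIndex;

static StrIndex make_index(const IntegerVector& strings) {
  StrIndex idx;
  idx.reserve(strings.size() * 2);
  for (int i = 0; i < strings.size(); ++i) idx[(uint32_t)strings[i]] = i;
  return idx;
}

// [[Rcpp::export]]
IntegerVector cpp_popcount(IntegerVector x) {
  IntegerVector out(x.size());
  for (int i = 0; i < x.size(); ++i) out[i] = popcnt((uint32_t)x[i]);
  return out;
}

// Single-excitation link table E_pr (including diagonal p == r number
// operators). Entry: target string ia <- source string ja via a^dag_p a_r,
// with fermionic sign. Links are grouped by the pair key p*norb + r:
// group_start/group_end give half-open ranges into the sorted arrays.
// [[Rcpp::export]]
List cpp_build_links(IntegerVector strings, int norb) {
  StrIndex idx = make_index(strings);
  int ns = strings.size();
  std::vector<int> ia, ja, pp, rr, sg;
  for (int j = 0; j < ns; ++j) {
    uint32_t J = (uint32_t)strings[j];
    for (int r = 0; r < norb; ++r) {
      if (!(J & (1u << r))) continue;
      // diagonal occupation link
      ia.push_back(j); ja.push_back(j); pp.push_back(r); rr.push_back(r);
      sg.push_back(1);
      uint32_t J1 = J ^ (1u << r);
      int par1 = parity_below(J, r);
      for (int p = 0; p < norb; ++p) {
        if (p == r || (J & (1u << p))) continue;
        uint32_t I = J1 | (1u << p);
        StrIndex::const_iterator it = idx.find(I);
        if (it == idx.end()) continue;
        int par = par1 + parity_below(J1, p);
        ia.push_back(it->second); ja.push_back(j);
        pp.push_back(p); rr.push_back(r);
        sg.push_back((par & 1) ? -1 : 1);
      }
    }
  }
  // counting sort by key = p*norb + r
  int nkey = norb * norb, nl = (int)ia.size();
  std::vector<int> count(nkey + 1, 0);
  for (int l = 0; l < nl; ++l) count[pp[l] * norb + rr[l] + 1]++;
  for (int k = 0; k < nkey; ++k) count[k + 1] += count[k];
  IntegerVector oia(nl), oja(nl), opp(nl), orr(nl), osg(nl);
  IntegerVector gs(nkey), ge(nkey);
  std::vector<int> pos(count.begin(), count.end() - 1);
  for (int l = 0; l < nl; ++l) {
    int key = pp[l] * norb + rr[l];
    int at = pos[key]++;
    oia[at] = ia[l]; oja[at] = ja[l]; opp[at] = pp[l]; orr[at] = rr[l];
    osg[at] = sg[l];
  }
  for (int k = 0; k < nkey; ++k) { gs[k] = count[k]; ge[k] = count[k + 1]; }
  return List::create(_["ia"] = oia, _["ja"] = oja, _["p"] = opp,
                      _["r"] = orr, _["sign"] = osg,
                      _["group_start"] = gs, _["group_end"] = ge,
                      _["n_strings"] = ns, _["norb"] = norb);
}

static inline double eri_at(const NumericVector& eri, int n, int p, int r,
                            int q, int s) {
  return eri[p + n * (r + n * (q + n * s))];
}

// Same-spin Hamiltonian over one spin species: h + the same-spin two-body
// part, as symmetric sparse triplets over the string list (diagonal
// included). Slater-Condon rules; phases by sequential operator application.
// [[Rcpp::export]]
List cpp_samespin_ham(IntegerVector strings, int norb, NumericMatrix h1,
                      NumericVector eri) {
  StrIndex idx = make_index(strings);
  int ns = strings.size();
  std::vector<int> ti, tj;
  std::vector<double> tv;
  std::vector<int> occ, vir;
  occ.reserve(norb); vir.reserve(norb);
  for (int j = 0; j < ns; ++j) {
    uint32_t J = (uint32_t)strings[j];
    occ.clear(); vir.clear();
    for (int p = 0; p < norb; ++p) {
      if (J & (1u << p)) occ.push_back(p); else vir.push_back(p);
    }
    int no = (int)occ.size(), nv = (int)vir.size();
    // diagonal
    double d = 0.0;
    for (int a = 0; a < no; ++a) {
      d += h1(occ[a], occ[a]);
      for (int b = a + 1; b < no; ++b)
        d += eri_at(eri, norb, occ[a], occ[a], occ[b], occ[b])
           - eri_at(eri, norb, occ[a], occ[b], occ[b], occ[a]);
    }
    ti.push_back(j); tj.push_back(j); tv.push_back(d);
    // singles r -> p
    for (int a = 0; a < no; ++a) {
      int r = occ[a];
      uint32_t J1 = J ^ (1u << r);
      int par1 = parity_below(J, r);
      for (int b = 0; b < nv; ++b) {
        int p = vir[b];
        uint32_t I = J1 | (1u << p);
        StrIndex::const_iterator it = idx.find(I);
        if (it == idx.end()) continue;
        double me = h1(p, r);
        for (int c = 0; c < no; ++c) {
          int q = occ[c];
          if (q == r) continue;
          me += eri_at(eri, norb, p, r, q, q)
              - eri_at(eri, norb, p, q, q, r);
        }
        int par = par1 + parity_below(J1, p);
        ti.push_back(it->second); tj.push_back(j);
        tv.push_back((par & 1) ? -me : me);
      }
    }
    // doubles {r,s} -> {p,q}, r < s, p < q
    for (int a = 0; a < no; ++a) {
      int r = occ[a];
      for (int b = a + 1; b < no; ++b) {
        int s = occ[b];
        // annihilate r then s
        int par = parity_below(J, r);
        uint32_t J1 = J ^ (1u << r);
        par += parity_below(J1, s);
        uint32_t J2 = J1 ^ (1u << s);
        for (int c = 0; c < nv; ++c) {
          int q = vir[c];
          int par2 = par + parity_below(J2, q);
          uint32_t J3 = J2 | (1u << q);
          for (int e = c + 1; e < nv; ++e) {
            int p = vir[e];
            uint32_t I = J3 | (1u << p);
            StrIndex::const_iterator it = idx.find(I);
            if (it == idx.end()) continue;
            int par3 = par2 + parity_below(J3, p);
            // <I| (1/2) sum (pr|qs) p+ q+ s r |J>, creation order a+_p a+_q
            double me = eri_at(eri, norb, p, r, q, s)
                      - eri_at(eri, norb, p, s, q, r);
            ti.push_back(it->second); tj.push_back(j);
            tv.push_back((par3 & 1) ? -me : me);
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["val"] = wrap(tv));
}

// out = H C (side = 0) or C H^T (side = 1) for sparse symmetric H given as
// triplets over the corresponding string list.
// [[Rcpp::export]]
NumericMatrix cpp_apply_spin(NumericMatrix C, IntegerVector ti,
                             IntegerVector tj, NumericVector tv, int side) {
  int na = C.nrow(), nb = C.ncol();
  NumericMatrix out(na, nb);
  int nl = ti.size();
  const double* c = C.begin();
  double* o = out.begin();
  if (side == 0) {
    for (int l = 0; l < nl; ++l) {
      int i = ti[l], j = tj[l];
      double v = tv[l];
      for (int b = 0; b < nb; ++b) o[i + na * b] += v * c[j + na * b];
    }
  } else {
    for (int l = 0; l < nl; ++l) {
      int i = ti[l], j = tj[l];
      double v = tv[l];
      double* ocol = o + na * (size_t)i;
      const double* ccol = c + na * (size_t)j;
      for (int a = 0; a < na; ++a) ocol[a] += v * ccol[a];
    }
  }
  return out;
}

// Opposite-spin two-body sigma:
//   sigma[Ia, Ib] += (pr|qs) * sa * sb * C[Ja, Jb]
// over alpha links (Ia <- Ja via E^a_pr) and beta links (Ib <- Jb via
// E^b_qs), both tables including diagonal number-operator links, so Coulomb
// diagonal-diagonal and diagonal-single cross terms are covered.
// [[Rcpp::export]]
NumericMatrix cpp_sigma_ab(NumericMatrix C, List la, List lb,
                           NumericVector eri, int norb) {
  int na = C.nrow(), nb = C.ncol();
  NumericMatrix out(na, nb);
  IntegerVector a_ia = la["ia"], a_ja = la["ja"], a_sg = la["sign"];
  IntegerVector a_gs = la["group_start"], a_ge = la["group_end"];
  IntegerVector b_ib = lb["ia"], b_jb = lb["ja"], b_sg = lb["sign"];
  IntegerVector b_gs = lb["group_start"], b_ge = lb["group_end"];
  const double* c = C.begin();
  double* o = out.begin();
  std::vector<int> rowmap(na, -1);
  std::vector<int> rows;
  std::vector<double> D, F;
  for (int p = 0; p < norb; ++p) {
    for (int r = 0; r < norb; ++r) {
      int key = p * norb + r;
      int s0 = a_gs[key], s1 = a_ge[key];
      if (s0 == s1) continue;
      // compact row set
      rows.clear();
      for (int l = s0; l < s1; ++l) {
        int ia = a_ia[l];
        if (rowmap[ia] < 0) { rowmap[ia] = (int)rows.size(); rows.push_back(ia); }
      }
      int R = (int)rows.size();
      D.assign((size_t)R * nb, 0.0);
      F.assign((size_t)R * nb, 0.0);
      for (int l = s0; l < s1; ++l) {
        int row = rowmap[a_ia[l]];
        int ja = a_ja[l];
        double sa = (double)a_sg[l];
        const double* crow = c + ja;
        for (int ib = 0; ib < nb; ++ib)
          D[row + (size_t)R * ib] += sa * crow[na * (size_t)ib];
      }
      // contract with integrals through beta links
      for (int q = 0; q < norb; ++q) {
        for (int s = 0; s < norb; ++s) {
          double g = eri_at(eri, norb, p, r, q, s);
          if (g == 0.0) continue;
          int bkey = q * norb + s;
          int t0 = b_gs[bkey], t1 = b_ge[bkey];
          for (int l = t0; l < t1; ++l) {
            int ib = b_ib[l], jb = b_jb[l];
            double f = g * (double)b_sg[l];
            double* Fc = F.data() + (size_t)R * ib;
            const double* Dc = D.data() + (size_t)R * jb;
            for (int x = 0; x < R; ++x) Fc[x] += f * Dc[x];
          }
        }
      }
      for (int x = 0; x < R; ++x) {
        int ia = rows[x];
        for (int ib = 0; ib < nb; ++ib)
          o[ia + na * (size_t)ib] += F[x + (size_t)R * ib];
      }
      for (int x = 0; x < R; ++x) rowmap[rows[x]] = -1;
    }
  }
  return out;
}

// S^2 applied to a factorized CI matrix:
//   S^2 = Sz^2 + N/2 - sum_{pq} E^a_{pq} E^b_{qp}
// using the same link tables (diagonal links give the n_pa n_pb term).
// [[Rcpp::export]]
NumericMatrix cpp_s2_apply(NumericMatrix C, List la, List lb, int norb,
                           int nalpha, int nbeta) {
  int na = C.nrow(), nb = C.ncol();
  double sz = 0.5 * (nalpha - nbeta);
  double d0 = sz * sz + 0.5 * (nalpha + nbeta);
  NumericMatrix out(na, nb);
  const double* c = C.begin();
  double* o = out.begin();
  for (size_t k = 0; k < (size_t)na * nb; ++k) o[k] = d0 * c[k];
  IntegerVector a_ia = la["ia"], a_ja = la["ja"], a_sg = la["sign"];
  IntegerVector a_gs = la["group_start"], a_ge = la["group_end"];
  IntegerVector b_ib = lb["ia"], b_jb = lb["ja"], b_sg = lb["sign"];
  IntegerVector b_gs = lb["group_start"], b_ge = lb["group_end"];
  for (int p = 0; p < norb; ++p) {
    for (int q = 0; q < norb; ++q) {
      int akey = p * norb + q;   // alpha: create p, annihilate q
      int bkey = q * norb + p;   // beta:  create q, annihilate p
      int s0 = a_gs[akey], s1 = a_ge[akey];
      if (s0 == s1) continue;
      int t0 = b_gs[bkey], t1 = b_ge[bkey];
      if (t0 == t1) continue;
      for (int l = s0; l < s1; ++l) {
        int ia = a_ia[l], ja = a_ja[l];
        double sa = (double)a_sg[l];
        for (int m = t0; m < t1; ++m) {
          int ib = b_ib[m], jb = b_jb[m];
          double v = sa * (double)b_sg[m];
          o[ia + na * (size_t)ib] -= v * c[ja + na * (size_t)jb];
        }
      }
    }
  }
  return out;
}

// Unique strings reachable from `strings` by at most `level` (1 or 2)
// single excitations, including the input strings. Sorted ascending.
// [[Rcpp::export]]
IntegerVector cpp_excite_strings(IntegerVector strings, int norb, int level) {
  std::unordered_map<uint32_t, char> seen;
  std::vector<uint32_t> base(strings.begin(), strings.end());
  for (size_t i = 0; i < base.size(); ++i) seen[base[i]] = 1;
  std::vector<uint32_t> cur = base;
  for (int lev = 0; lev < level; ++lev) {
    std::vector<uint32_t> next;
    for (size_t i = 0; i < cur.size(); ++i) {
      uint32_t J = cur[i];
      for (int r = 0; r < norb; ++r) {
        if (!(J & (1u << r))) continue;
        uint32_t J1 = J ^ (1u << r);
        for (int p = 0; p < norb; ++p) {
          if (J1 & (1u << p)) continue;
          uint32_t I = J1 | (1u << p);
          if (seen.insert(std::make_pair(I, 1)).second) next.push_back(I);
        }
      }
    }
    cur.swap(next);
  }
  std::vector<uint32_t> all;
  all.reserve(seen.size());
  for (std::unordered_map<uint32_t, char>::iterator it = seen.begin();
       it != seen.end(); ++it)
    all.push_back(it->first);
  std::sort(all.begin(), all.end());
  IntegerVector out(all.size());
  for (size_t i = 0; i < all.size(); ++i) out[i] = (int)all[i];
  return out;
}
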