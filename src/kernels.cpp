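// Compute kernels for the cutoff-scheme MD engine.
//
// Conventions shared with the R layer:
//   * all atom / entity indices crossing the boundary are 0-based,
//   * positions are unwrapped (minimum image is applied per interaction,
//     never to stored coordinates), boxes are orthorhombic,
//   * units: nm, ps, u, e, kJ/mol.

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static inline double min_image_1d(double d, double box) {
  return d - box * std::round(d / box);
}

// hot-loop variant: reciprocal multiply + nearbyint (round-to-nearest-even;
// ties can only occur at exactly half a box length, which the minimum-image
// validity bound already excludes for interacting pairs)
static inline double min_image_fast(double d, double box, double inv_box) {
  return d - box * std::nearbyint(d * inv_box);
}

// [[Rcpp::export]]
NumericMatrix cpp_entity_centers(const NumericMatrix& pos,
                                 const IntegerVector& ent_ptr,
                                 const IntegerVector& ent_atoms,
                                 const IntegerVector& ent_center_atom) {
  const int ne = ent_ptr.size() - 1;
  NumericMatrix out(ne, 3);
  for (int e = 0; e < ne; ++e) {
    const int ca = ent_center_atom[e];
    if (ca >= 0) {
      for (int k = 0; k < 3; ++k) out(e, k) = pos(ca, k);
    } else {
      double c[3] = {0.0, 0.0, 0.0};
      const int n = ent_ptr[e + 1] - ent_ptr[e];
      for (int a = ent_ptr[e]; a < ent_ptr[e + 1]; ++a) {
        const int i = ent_atoms[a];
        for (int k = 0; k < 3; ++k) c[k] += pos(i, k);
      }
      for (int k = 0; k < 3; ++k) out(e, k) = c[k] / n;
    }
  }
  return out;
}

static List pairs_to_list(const std::vector<int>& s, const std::vector<int>& m) {
  IntegerMatrix ms((int)(s.size() / 2), 2), mm((int)(m.size() / 2), 2);
  for (int p = 0; p < ms.nrow(); ++p) { ms(p, 0) = s[2 * p]; ms(p, 1) = s[2 * p + 1]; }
  for (int p = 0; p < mm.nrow(); ++p) { mm(p, 0) = m[2 * p]; mm(p, 1) = m[2 * p + 1]; }
  return List::create(_["short_pairs"] = ms, _["intermediate_pairs"] = mm);
}

// Strictly-less-than inclusion at R_short; half-open shell [R_short, R_long).
// [[Rcpp::export]]
List cpp_pairlist_brute(const NumericMatrix& centers, const NumericVector& box,
                        double r_short, double r_long) {
  const int n = centers.nrow();
  const double rs2 = r_short * r_short, rl2 = r_long * r_long;
  const double inv_box[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};
  std::vector<int> sp, ip;
  for (int i = 0; i < n - 1; ++i) {
    const double xi = centers(i, 0), yi = centers(i, 1), zi = centers(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = min_image_fast(xi - centers(j, 0), box[0], inv_box[0]);
      const double dy = min_image_fast(yi - centers(j, 1), box[1], inv_box[1]);
      const double dz = min_image_fast(zi - centers(j, 2), box[2], inv_box[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < rs2) { sp.push_back(i); sp.push_back(j); }
      else if (r2 < rl2) { ip.push_back(i); ip.push_back(j); }
    }
  }
  return pairs_to_list(sp, ip);
}

// Cell-list classification; requires >= 3 cells of edge >= r_long per
// dimension (the R wrapper falls back to the brute-force path otherwise).
// [[Rcpp::export]]
List cpp_pairlist_cell(const NumericMatrix& centers, const NumericVector& box,
                       double r_short, double r_long) {
  const int n = centers.nrow();
  const double rs2 = r_short * r_short, rl2 = r_long * r_long;
  const double inv_box[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};
  int nc[3];
  double clen[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = (int)std::floor(box[k] / r_long);
    if (nc[k] < 3) stop("cell list requires at least 3 cells per dimension");
    clen[k] = box[k] / nc[k];
  }
  const int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int> > cells(ncell);
  std::vector<int> cidx(n);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double x = centers(i, k);
      x -= box[k] * std::floor(x / box[k]);  // wrap into [0, box)
      int ck = (int)(x / clen[k]);
      if (ck >= nc[k]) ck = nc[k] - 1;
      c[k] = ck;
    }
    int id = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cidx[i] = id;
    cells[id].push_back(i);
  }
  std::vector<int> sp, ip;
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        const int c1 = (cz * nc[1] + cy) * nc[0] + cx;
        const std::vector<int>& a1 = cells[c1];
        if (a1.empty()) continue;
        for (int oz = -1; oz <= 1; ++oz)
          for (int oy = -1; oy <= 1; ++oy)
            for (int ox = -1; ox <= 1; ++ox) {
              const int nx = (cx + ox + nc[0]) % nc[0];
              const int ny = (cy + oy + nc[1]) % nc[1];
              const int nz = (cz + oz + nc[2]) % nc[2];
              const int c2 = (nz * nc[1] + ny) * nc[0] + nx;
              if (c2 < c1) continue;  // each cell pair visited once
              const std::vector<int>& a2 = cells[c2];
              for (size_t u = 0; u < a1.size(); ++u) {
                const int i = a1[u];
                const double xi = centers(i, 0), yi = centers(i, 1), zi = centers(i, 2);
                const size_t vstart = (c2 == c1) ? u + 1 : 0;
                for (size_t v = vstart; v < a2.size(); ++v) {
                  const int j = a2[v];
                  const double dx = min_image_fast(xi - centers(j, 0), box[0], inv_box[0]);
                  const double dy = min_image_fast(yi - centers(j, 1), box[1], inv_box[1]);
                  const double dz = min_image_fast(zi - centers(j, 2), box[2], inv_box[2]);
                  const double r2 = dx * dx + dy * dy + dz * dz;
                  const int lo = i < j ? i : j, hi = i < j ? j : i;
                  if (r2 < rs2) { sp.push_back(lo); sp.push_back(hi); }
                  else if (r2 < rl2) { ip.push_back(lo); ip.push_back(hi); }
                }
              }
            }
      }
  return pairs_to_list(sp, ip);
}

// Shared accumulator state for the nonbonded inner loop; coordinates are
// copied once into contiguous per-atom triples and forces accumulated the
// same way, so the hot loop never touches R matrices.
struct NBAccum {
  double eel[3];
  double elj[3];
  double wsum;
  std::vector<double> xyz;
  std::vector<double> force;
  NBAccum(const NumericMatrix& pos) : xyz(3 * pos.nrow()), force(3 * pos.nrow(), 0.0) {
    eel[0] = eel[1] = eel[2] = 0.0;
    elj[0] = elj[1] = elj[2] = 0.0;
    wsum = 0.0;
    const int n = pos.nrow();
    for (int i = 0; i < n; ++i) {
      xyz[3 * i] = pos(i, 0); xyz[3 * i + 1] = pos(i, 1); xyz[3 * i + 2] = pos(i, 2);
    }
  }
};

// All atom-atom interactions between two entities, accumulated in a fixed
// member order so every caller produces bit-identical sums.
static inline void eval_entity_pair(
    int ei, int ej,
    const IntegerVector& ent_ptr, const IntegerVector& ent_atoms,
    const NumericVector& charge, const IntegerVector& lj_type,
    const NumericMatrix& c6, const NumericMatrix& c12,
    const IntegerVector& subsys, const IntegerVector& mol,
    const double* box, const double* inv_box,
    double c_rf, double rrf2, double k_rf, double inv_rrf, double c_over_rrf3,
    double f_elec, const std::unordered_set<int64_t>& exset, int natoms,
    NBAccum& acc) {
  const double* P = acc.xyz.data();
  double* F = acc.force.data();
  for (int ai = ent_ptr[ei]; ai < ent_ptr[ei + 1]; ++ai) {
    const int a = ent_atoms[ai];
    const double xa = P[3 * a], ya = P[3 * a + 1], za = P[3 * a + 2];
    const double qa = charge[a];
    const int ta = lj_type[a], sa = subsys[a], ma = mol[a];
    for (int bj = ent_ptr[ej]; bj < ent_ptr[ej + 1]; ++bj) {
      const int b = ent_atoms[bj];
      if (ma == mol[b]) {
        int lo = a < b ? a : b, hi = a < b ? b : a;
        if (a == b || exset.count((int64_t)lo * natoms + hi)) continue;
      }
      double dx = min_image_fast(xa - P[3 * b], box[0], inv_box[0]);
      double dy = min_image_fast(ya - P[3 * b + 1], box[1], inv_box[1]);
      double dz = min_image_fast(za - P[3 * b + 2], box[2], inv_box[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double inv_r = 1.0 / std::sqrt(r2);
      const double inv_r2 = inv_r * inv_r;
      const int cls = sa + subsys[b];
      double fscal = 0.0;
      const double qq = qa * charge[b];
      if (qq != 0.0) {
        // algebraically identical to 1/r - Crf r^2/(2 Rrf^3) - (1 - Crf/2)/Rrf,
        // arranged to vanish exactly (in floating point) at r = Rrf
        acc.eel[cls] += f_elec * qq * ((inv_r - inv_rrf) - k_rf * (r2 - rrf2));
        fscal += f_elec * qq * (inv_r2 * inv_r + c_over_rrf3);
      }
      const double C6 = c6(ta, lj_type[b]);
      const double C12 = c12(ta, lj_type[b]);
      if (C6 != 0.0 || C12 != 0.0) {
        const double ir6 = inv_r2 * inv_r2 * inv_r2;
        acc.elj[cls] += C12 * ir6 * ir6 - C6 * ir6;
        fscal += (12.0 * C12 * ir6 * ir6 - 6.0 * C6 * ir6) * inv_r2;
      }
      if (fscal != 0.0) {
        F[3 * a] += fscal * dx; F[3 * a + 1] += fscal * dy; F[3 * a + 2] += fscal * dz;
        F[3 * b] -= fscal * dx; F[3 * b + 1] -= fscal * dy; F[3 * b + 2] -= fscal * dz;
        acc.wsum += fscal * r2;  // r_ij . F_i
      }
    }
  }
}

static std::unordered_set<int64_t> exclusion_set(const IntegerMatrix& excl,
                                                 int natoms) {
  std::unordered_set<int64_t> exset;
  exset.reserve(excl.nrow() * 2 + 1);
  for (int p = 0; p < excl.nrow(); ++p) {
    int a = excl(p, 0), b = excl(p, 1);
    if (a > b) std::swap(a, b);
    exset.insert((int64_t)a * natoms + b);
  }
  return exset;
}

static List nb_result(const NBAccum& acc) {
  const int n = (int)acc.force.size() / 3;
  NumericMatrix forces(n, 3);
  for (int i = 0; i < n; ++i) {
    forces(i, 0) = acc.force[3 * i];
    forces(i, 1) = acc.force[3 * i + 1];
    forces(i, 2) = acc.force[3 * i + 2];
  }
  return List::create(_["e_el"] = NumericVector::create(acc.eel[0], acc.eel[1], acc.eel[2]),
                      _["e_lj"] = NumericVector::create(acc.elj[0], acc.elj[1], acc.elj[2]),
                      _["forces"] = forces,
                      _["virial"] = -0.5 * acc.wsum);
}

// Reaction-field + Lennard-Jones evaluation over a list of entity pairs.
// All atom pairs of two listed entities interact at their atomic minimum-image
// distance (this is what makes group cutoffs discontinuous at the center
// crossing); excluded intramolecular pairs are skipped.  Energies are
// accumulated into solute-solute / solute-solvent / solvent-solvent slots by
// the per-atom subsystem labels (0 = solute, 1 = solvent).
// [[Rcpp::export]]
List cpp_eval_pairs(const NumericMatrix& pos, const IntegerMatrix& pairs,
                    const IntegerVector& ent_ptr, const IntegerVector& ent_atoms,
                    const NumericVector& charge, const IntegerVector& lj_type,
                    const NumericMatrix& c6, const NumericMatrix& c12,
                    const IntegerVector& subsys, const IntegerVector& mol,
                    const NumericVector& box, double c_rf, double r_rf,
                    double f_elec, const IntegerMatrix& excl) {
  const int natoms = pos.nrow();
  const std::unordered_set<int64_t> exset = exclusion_set(excl, natoms);
  const double rrf2 = r_rf * r_rf;
  const double rrf3 = rrf2 * r_rf;
  const double inv_rrf = 1.0 / r_rf;
  const double k_rf = 0.5 * c_rf / rrf3;
  const double c_over_rrf3 = c_rf / rrf3;
  const double inv_box[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};
  NBAccum acc(pos);
  for (int p = 0; p < pairs.nrow(); ++p)
    eval_entity_pair(pairs(p, 0), pairs(p, 1), ent_ptr, ent_atoms,
                     charge, lj_type, c6, c12, subsys, mol, &box[0], inv_box,
                     c_rf, rrf2, k_rf, inv_rrf, c_over_rrf3, f_elec, exset,
                     natoms, acc);
  return nb_result(acc);
}

// Fused single-range path: classify entity-centre pairs against one cutoff
// and evaluate them in the same i < j order a canonical pairlist would use,
// so the result is bit-identical to building the list first.
// [[Rcpp::export]]
List cpp_sr_nonbonded(const NumericMatrix& pos,
                      const IntegerVector& ent_ptr, const IntegerVector& ent_atoms,
                      const IntegerVector& ent_center_atom,
                      const NumericVector& charge, const IntegerVector& lj_type,
                      const NumericMatrix& c6, const NumericMatrix& c12,
                      const IntegerVector& subsys, const IntegerVector& mol,
                      const NumericVector& box, double r_cut,
                      double c_rf, double r_rf, double f_elec,
                      const IntegerMatrix& excl) {
  const int natoms = pos.nrow();
  const int ne = ent_ptr.size() - 1;
  const std::unordered_set<int64_t> exset = exclusion_set(excl, natoms);
  const double rrf2 = r_rf * r_rf;
  const double rrf3 = rrf2 * r_rf;
  const double inv_rrf = 1.0 / r_rf;
  const double k_rf = 0.5 * c_rf / rrf3;
  const double c_over_rrf3 = c_rf / rrf3;
  const double rc2 = r_cut * r_cut;
  const double inv_box[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};
  NumericMatrix centers = cpp_entity_centers(pos, ent_ptr, ent_atoms,
                                             ent_center_atom);
  NBAccum acc(pos);
  for (int i = 0; i < ne - 1; ++i) {
    const double xi = centers(i, 0), yi = centers(i, 1), zi = centers(i, 2);
    for (int j = i + 1; j < ne; ++j) {
      const double dx = min_image_fast(xi - centers(j, 0), box[0], inv_box[0]);
      const double dy = min_image_fast(yi - centers(j, 1), box[1], inv_box[1]);
      const double dz = min_image_fast(zi - centers(j, 2), box[2], inv_box[2]);
      if (dx * dx + dy * dy + dz * dz >= rc2) continue;
      eval_entity_pair(i, j, ent_ptr, ent_atoms, charge, lj_type, c6, c12,
                       subsys, mol, &box[0], inv_box, c_rf, rrf2, k_rf,
                       inv_rrf, c_over_rrf3, f_elec, exset, natoms, acc);
    }
  }
  return nb_result(acc);
}

// Flattened single-range path for fully atomistic entity sets: every atom is
// its own entity, so the centre test and the atomic interaction coincide and
// one pass over atom pairs does both.  Pair order and per-pair arithmetic are
// identical to the generic path, so results are bit-identical.
// [[Rcpp::export]]
List cpp_sr_nonbonded_atomistic(const NumericMatrix& pos,
                                const NumericVector& charge,
                                const IntegerVector& lj_type,
                                const NumericMatrix& c6, const NumericMatrix& c12,
                                const IntegerVector& subsys, const IntegerVector& mol,
                                const NumericVector& box, double r_cut,
                                double c_rf, double r_rf, double f_elec,
                                const IntegerMatrix& excl) {
  const int n = pos.nrow();
  const std::unordered_set<int64_t> exset = exclusion_set(excl, n);
  const double rrf2 = r_rf * r_rf;
  const double rrf3 = rrf2 * r_rf;
  const double inv_rrf = 1.0 / r_rf;
  const double k_rf = 0.5 * c_rf / rrf3;
  const double c_over_rrf3 = c_rf / rrf3;
  const double rc2 = r_cut * r_cut;
  const double inv_box[3] = {1.0 / box[0], 1.0 / box[1], 1.0 / box[2]};
  const double bx = box[0], by = box[1], bz = box[2];
  const double ibx = inv_box[0], iby = inv_box[1], ibz = inv_box[2];
  // column-contiguous copies for the inner scan
  std::vector<double> X(n), Y(n), Z(n), F(3 * n, 0.0);
  for (int i = 0; i < n; ++i) { X[i] = pos(i, 0); Y[i] = pos(i, 1); Z[i] = pos(i, 2); }
  double eel[3] = {0, 0, 0}, elj[3] = {0, 0, 0}, wsum = 0.0;
  for (int a = 0; a < n - 1; ++a) {
    const double xa = X[a], ya = Y[a], za = Z[a];
    const double qa = charge[a];
    const int ta = lj_type[a], sa = subsys[a], ma = mol[a];
    double fax = 0.0, fay = 0.0, faz = 0.0;
    for (int b = a + 1; b < n; ++b) {
      double dx = xa - X[b]; dx -= bx * std::nearbyint(dx * ibx);
      double dy = ya - Y[b]; dy -= by * std::nearbyint(dy * iby);
      double dz = za - Z[b]; dz -= bz * std::nearbyint(dz * ibz);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      if (ma == mol[b] && exset.count((int64_t)a * n + b)) continue;
      const double inv_r = 1.0 / std::sqrt(r2);
      const double inv_r2 = inv_r * inv_r;
      const int cls = sa + subsys[b];
      double fscal = 0.0;
      const double qq = qa * charge[b];
      if (qq != 0.0) {
        eel[cls] += f_elec * qq * ((inv_r - inv_rrf) - k_rf * (r2 - rrf2));
        fscal += f_elec * qq * (inv_r2 * inv_r + c_over_rrf3);
      }
      const double C6 = c6(ta, lj_type[b]);
      const double C12 = c12(ta, lj_type[b]);
      if (C6 != 0.0 || C12 != 0.0) {
        const double ir6 = inv_r2 * inv_r2 * inv_r2;
        elj[cls] += C12 * ir6 * ir6 - C6 * ir6;
        fscal += (12.0 * C12 * ir6 * ir6 - 6.0 * C6 * ir6) * inv_r2;
      }
      if (fscal != 0.0) {
        fax += fscal * dx; fay += fscal * dy; faz += fscal * dz;
        F[3 * b] -= fscal * dx; F[3 * b + 1] -= fscal * dy; F[3 * b + 2] -= fscal * dz;
        wsum += fscal * r2;
      }
    }
    F[3 * a] += fax; F[3 * a + 1] += fay; F[3 * a + 2] += faz;
  }
  NumericMatrix forces(n, 3);
  for (int i = 0; i < n; ++i) {
    forces(i, 0) = F[3 * i]; forces(i, 1) = F[3 * i + 1]; forces(i, 2) = F[3 * i + 2];
  }
  return List::create(_["e_el"] = NumericVector::create(eel[0], eel[1], eel[2]),
                      _["e_lj"] = NumericVector::create(elj[0], elj[1], elj[2]),
                      _["forces"] = forces,
                      _["virial"] = -0.5 * wsum);
}

// Iterative SHAKE: restore constrained distances relative to the reference
// geometry until |d^2 - d0^2| / d0^2 <= tol for every constraint.
// [[Rcpp::export]]
List cpp_shake(const NumericMatrix& pos_new, const NumericMatrix& pos_ref,
               const IntegerVector& ci, const IntegerVector& cj,
               const NumericVector& d0, const NumericVector& inv_mass,
               double tol, int max_iter) {
  NumericMatrix p = clone(pos_new);
  const int nc = ci.size();
  int iter = 0;
  bool done = false;
  while (!done && iter < max_iter) {
    done = true;
    ++iter;
    for (int c = 0; c < nc; ++c) {
      const int i = ci[c], j = cj[c];
      const double dx = p(i, 0) - p(j, 0);
      const double dy = p(i, 1) - p(j, 1);
      const double dz = p(i, 2) - p(j, 2);
      const double d02 = d0[c] * d0[c];
      const double diff = dx * dx + dy * dy + dz * dz - d02;
      if (std::fabs(diff) > tol * d02) {
        done = false;
        const double rx = pos_ref(i, 0) - pos_ref(j, 0);
        const double ry = pos_ref(i, 1) - pos_ref(j, 1);
        const double rz = pos_ref(i, 2) - pos_ref(j, 2);
        const double dot = dx * rx + dy * ry + dz * rz;
        const double g = diff / (2.0 * (inv_mass[i] + inv_mass[j]) * dot);
        p(i, 0) -= g * inv_mass[i] * rx; p(i, 1) -= g * inv_mass[i] * ry; p(i, 2) -= g * inv_mass[i] * rz;
        p(j, 0) += g * inv_mass[j] * rx; p(j, 1) += g * inv_mass[j] * ry; p(j, 2) += g * inv_mass[j] * rz;
      }
    }
  }
  double max_dev = 0.0;
  for (int c = 0; c < nc; ++c) {
    const int i = ci[c], j = cj[c];
    const double dx = p(i, 0) - p(j, 0);
    const double dy = p(i, 1) - p(j, 1);
    const double dz = p(i, 2) - p(j, 2);
    const double d02 = d0[c] * d0[c];
    const double dev = std::fabs(dx * dx + dy * dy + dz * dz - d02) / d02;
    if (dev > max_dev) max_dev = dev;
  }
  return List::create(_["positions"] = p, _["iterations"] = iter,
                      _["converged"] = done, _["max_rel_dev"] = max_dev);
}

// Remove relative velocity components along constrained bonds (applied after
// random velocity assignment so rigid molecules carry no internal motion).
// [[Rcpp::export]]
NumericMatrix cpp_project_velocities(const NumericMatrix& vel, const NumericMatrix& pos,
                                     const IntegerVector& ci, const IntegerVector& cj,
                                     const NumericVector& inv_mass,
                                     double tol, int max_iter) {
  NumericMatrix v = clone(vel);
  const int nc = ci.size();
  for (int iter = 0; iter < max_iter; ++iter) {
    double worst = 0.0;
    for (int c = 0; c < nc; ++c) {
      const int i = ci[c], j = cj[c];
      const double dx = pos(i, 0) - pos(j, 0);
      const double dy = pos(i, 1) - pos(j, 1);
      const double dz = pos(i, 2) - pos(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rv = (v(i, 0) - v(j, 0)) * dx + (v(i, 1) - v(j, 1)) * dy +
                        (v(i, 2) - v(j, 2)) * dz;
      const double resid = std::fabs(rv) / std::sqrt(d2);
      if (resid > worst) worst = resid;
      const double g = rv / (d2 * (inv_mass[i] + inv_mass[j]));
      v(i, 0) -= g * inv_mass[i] * dx; v(i, 1) -= g * inv_mass[i] * dy; v(i, 2) -= g * inv_mass[i] * dz;
      v(j, 0) += g * inv_mass[j] * dx; v(j, 1) += g * inv_mass[j] * dy; v(j, 2) += g * inv_mass[j] * dz;
    }
    if (worst < tol) break;
  }
  return v;
}

// Minimum over all minimum-image pair distances (builder overlap checks).
// [[Rcpp::export]]
double cpp_min_pair_distance(const NumericMatrix& pos, const NumericVector& box) {
  const int n = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = min_image_1d(pos(i, 0) - pos(j, 0), box[0]);
      const double dy = min_image_1d(pos(i, 1) - pos(j, 1), box[1]);
      const double dz = min_image_1d(pos(i, 2) - pos(j, 2), box[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < best) best = r2;
    }
  return std::sqrt(best);
}

// Histogram of minimum-image pair distances for the RDF.  With same = true
// (identical selections) each unordered pair is counted once.
// [[Rcpp::export]]
NumericVector cpp_pair_hist(const NumericMatrix& pos, const IntegerVector& sel_a,
                            const IntegerVector& sel_b, bool same,
                            const NumericVector& box, double bin_width, int n_bins) {
  NumericVector counts(n_bins);
  const double rmax = bin_width * n_bins;
  const double rmax2 = rmax * rmax;
  const int na = sel_a.size(), nb = sel_b.size();
  for (int u = 0; u < na; ++u) {
    const int i = sel_a[u];
    const double xi = pos(i, 0), yi = pos(i, 1), zi = pos(i, 2);
    const int vstart = same ? u + 1 : 0;
    for (int v = vstart; v < nb; ++v) {
      const int j = sel_b[v];
      if (j == i) continue;
      const double dx = min_image_1d(xi - pos(j, 0), box[0]);
      const double dy = min_image_1d(yi - pos(j, 1), box[1]);
      const double dz = min_image_1d(zi - pos(j, 2), box[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rmax2) continue;
      int b = (int)(std::sqrt(r2) / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      counts[b] += 1.0;
    }
  }
  return counts;
}

// Accumulate dipole-dipole dot products binned by site-site distance.
// [[Rcpp::export]]
List cpp_dipole_corr_hist(const NumericMatrix& sites, const NumericMatrix& mu,
                          const NumericVector& box, double bin_width, int n_bins) {
  NumericVector sums(n_bins), counts(n_bins);
  const double rmax = bin_width * n_bins;
  const double rmax2 = rmax * rmax;
  const int n = sites.nrow();
  for (int i = 0; i < n - 1; ++i) {
    const double xi = sites(i, 0), yi = sites(i, 1), zi = sites(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = min_image_1d(xi - sites(j, 0), box[0]);
      const double dy = min_image_1d(yi - sites(j, 1), box[1]);
      const double dz = min_image_1d(zi - sites(j, 2), box[2]);
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rmax2) continue;
      int b = (int)(std::sqrt(r2) / bin_width);
      if (b >= n_bins) b = n_bins - 1;
      sums[b] += mu(i, 0) * mu(j, 0) + mu(i, 1) * mu(j, 1) + mu(i, 2) * mu(j, 2);
      counts[b] += 1.0;
    }
  }
  return List::create(_["sums"] = sums, _["counts"] = counts);
}
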