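// Rotation-based attenuated forward/back projector with distance-dependent
// Gaussian collimator-detector response.
//
// Conventions (shared with the R wrappers):
//  * volumes are column-major arrays [nx, ny, nz]; x is the transaxial
//    detector axis u, z the axial detector axis v, y the projection axis;
//  * the camera rotates about z; for view angle a the volume is resampled
//    (bilinear, gather) into the view frame where the detector sits on the
//    +y side at distance `orbit` from the rotation centre;
//  * attenuation uses a half-voxel offset: a photon emitted in plane iy sees
//    half of its own plane's mu plus all planes nearer the detector;
//  * the activity is splatted (scatter/distribution) into the view frame,
//    which conserves each voxel's total exactly; the backprojector uses the
//    matching gather, so the pair is an exact transpose; the attenuation map
//    is gather-sampled identically in both directions;
//  * the per-plane blur kernel is a truncated, normalised Gaussian applied
//    with zero padding (symmetric, hence self-adjoint);
//  * detector bins are an integer `rebin` multiple of the voxel pitch
//    (block sum); the adjoint of the block sum is replication.
// The backprojector is the exact matrix transpose of the forward operator
// (gather rotation transposed to scatter), so the dot-product test holds to
// floating rounding.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Kernel {
  int radius;
  std::vector<double> w; // length 2*radius+1, sums to 1
};

Kernel make_kernel(double sigma_vox) {
  Kernel k;
  if (sigma_vox < 1e-8) {
    k.radius = 0;
    k.w.assign(1, 1.0);
    return k;
  }
  k.radius = (int)std::ceil(3.5 * sigma_vox);
  if (k.radius < 1) k.radius = 1;
  k.w.resize(2 * k.radius + 1);
  double s = 0.0;
  for (int i = -k.radius; i <= k.radius; ++i) {
    double v = std::exp(-0.5 * (double)i * i / (sigma_vox * sigma_vox));
    k.w[i + k.radius] = v;
    s += v;
  }
  for (double &v : k.w) v /= s;
  return k;
}

// separable blur of plane a[nx, nz] (x fastest) into out; tmp is scratch
void blur_plane(const double *a, double *out, double *tmp, int nx, int nz,
                const Kernel &k, bool renorm = false) {
  const int r = k.radius;
  if (r == 0) {
    std::copy(a, a + (size_t)nx * nz, out);
    return;
  }
  // along x
  for (int iz = 0; iz < nz; ++iz) {
    const double *row = a + (size_t)iz * nx;
    double *trow = tmp + (size_t)iz * nx;
    for (int ix = 0; ix < nx; ++ix) {
      double acc = 0.0, wsum = 0.0;
      int lo = ix - r < 0 ? -ix : -r;
      int hi = ix + r >= nx ? nx - 1 - ix : r;
      for (int d = lo; d <= hi; ++d) {
        acc += row[ix + d] * k.w[d + r];
        wsum += k.w[d + r];
      }
      trow[ix] = renorm ? acc / wsum : acc;
    }
  }
  // along z
  for (int iz = 0; iz < nz; ++iz) {
    int lo = iz - r < 0 ? -iz : -r;
    int hi = iz + r >= nz ? nz - 1 - iz : r;
    double *orow = out + (size_t)iz * nx;
    for (int ix = 0; ix < nx; ++ix) {
      double acc = 0.0, wsum = 0.0;
      for (int d = lo; d <= hi; ++d) {
        acc += tmp[(size_t)(iz + d) * nx + ix] * k.w[d + r];
        wsum += k.w[d + r];
      }
      orow[ix] = renorm ? acc / wsum : acc;
    }
  }
}

// gather-rotate volume about z by angle: out(ix,iy,iz) = vol sampled at the
// rotated coordinates (bilinear); optionally accumulates into out
void rotate_gather(const double *vol, double *out, int nx, int ny, int nz,
                   double ca, double sa, bool add = false) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  for (int iz = 0; iz < nz; ++iz) {
    const double *vz = vol + (size_t)iz * nx * ny;
    double *oz = out + (size_t)iz * nx * ny;
    for (int iy = 0; iy < ny; ++iy) {
      double dy = iy - cy;
      for (int ix = 0; ix < nx; ++ix) {
        double dx = ix - cx;
        double sx = cx + ca * dx - sa * dy;
        double sy = cy + sa * dx + ca * dy;
        double val = 0.0;
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        double fx = sx - x0, fy = sy - y0;
        for (int jy = 0; jy <= 1; ++jy) {
          int yy = y0 + jy;
          if (yy < 0 || yy >= ny) continue;
          double wy = jy ? fy : 1.0 - fy;
          for (int jx = 0; jx <= 1; ++jx) {
            int xx = x0 + jx;
            if (xx < 0 || xx >= nx) continue;
            double wx = jx ? fx : 1.0 - fx;
            val += wx * wy * vz[yy * (size_t)nx + xx];
          }
        }
        if (add) oz[iy * (size_t)nx + ix] += val;
        else oz[iy * (size_t)nx + ix] = val;
      }
    }
  }
}

// transpose of rotate_gather: splat values to their rotated positions
// (mass-conserving: the weights a voxel distributes sum to 1, so a point
// source keeps its exact total). Used as the forward rotation.
void rotate_scatter(const double *rot, double *vol, int nx, int ny, int nz,
                    double ca, double sa) {
  const double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1);
  for (int iz = 0; iz < nz; ++iz) {
    const double *rz = rot + (size_t)iz * nx * ny;
    double *vz = vol + (size_t)iz * nx * ny;
    for (int iy = 0; iy < ny; ++iy) {
      double dy = iy - cy;
      for (int ix = 0; ix < nx; ++ix) {
        double val = rz[iy * (size_t)nx + ix];
        if (val == 0.0) continue;
        double dx = ix - cx;
        double sx = cx + ca * dx - sa * dy;
        double sy = cy + sa * dx + ca * dy;
        int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy);
        double fx = sx - x0, fy = sy - y0;
        for (int jy = 0; jy <= 1; ++jy) {
          int yy = y0 + jy;
          if (yy < 0 || yy >= ny) continue;
          double wy = jy ? fy : 1.0 - fy;
          for (int jx = 0; jx <= 1; ++jx) {
            int xx = x0 + jx;
            if (xx < 0 || xx >= nx) continue;
            double wx = jx ? fx : 1.0 - fx;
            vz[yy * (size_t)nx + xx] += wx * wy * val;
          }
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".lq_forward")]]
NumericVector lq_forward(NumericVector act, NumericVector mu,
                         IntegerVector dim, double voxel_mm,
                         NumericVector angles, NumericVector orbit_mm,
                         double sigma0, double slope, int rebin,
                         bool use_att, bool use_rr) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nv = angles.size();
  if (nx % rebin != 0 || nz % rebin != 0)
    stop("grid dims must be divisible by the rebin factor");
  const int nu = nx / rebin, nw = nz / rebin;
  const double dl_cm = voxel_mm / 10.0; // mu is cm^-1
  const double cyc = 0.5 * (ny - 1);

  NumericVector out((size_t)nu * nw * nv);
  std::vector<double> rotA((size_t)nx * ny * nz), rotM;
  if (use_att) rotM.resize((size_t)nx * ny * nz);
  std::vector<double> plane((size_t)nx * nz), bl((size_t)nx * nz),
      tmp((size_t)nx * nz), attline((size_t)nx * nz);

  for (int v = 0; v < nv; ++v) {
    double ca = std::cos(angles[v]), sa = std::sin(angles[v]);
    std::fill(rotA.begin(), rotA.end(), 0.0);
    rotate_scatter(REAL(act), rotA.data(), nx, ny, nz, ca, sa);
    if (use_att) rotate_gather(REAL(mu), rotM.data(), nx, ny, nz, ca, sa);
    std::fill(attline.begin(), attline.end(), 0.0);
    std::vector<double> P((size_t)nx * nz, 0.0);
    for (int iy = ny - 1; iy >= 0; --iy) {
      // weighted emission plane
      for (int iz = 0; iz < nz; ++iz)
        for (int ix = 0; ix < nx; ++ix) {
          size_t pi = (size_t)iz * nx + ix;
          size_t vi = (size_t)iz * nx * ny + (size_t)iy * nx + ix;
          double w = 1.0;
          if (use_att) {
            double m = rotM[vi];
            w = std::exp(-(attline[pi] + 0.5 * m * dl_cm));
            attline[pi] += m * dl_cm;
          }
          plane[pi] = rotA[vi] * w;
        }
      double dist = orbit_mm[v] - (iy - cyc) * voxel_mm;
      if (dist < 0) dist = 0;
      double sig = use_rr ? (sigma0 + slope * dist) / voxel_mm : 0.0;
      Kernel k = make_kernel(sig);
      blur_plane(plane.data(), bl.data(), tmp.data(), nx, nz, k);
      for (size_t i = 0; i < P.size(); ++i) P[i] += bl[i];
    }
    // block-sum rebin
    double *ov = REAL(out) + (size_t)v * nu * nw;
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix)
        ov[(size_t)(iz / rebin) * nu + (ix / rebin)] +=
            P[(size_t)iz * nx + ix];
  }
  out.attr("dim") = IntegerVector::create(nu, nw, nv);
  return out;
}

// [[Rcpp::export(name = ".lq_back")]]
NumericVector lq_back(NumericVector sino, NumericVector mu,
                      IntegerVector dim, double voxel_mm,
                      NumericVector angles, NumericVector orbit_mm,
                      double sigma0, double slope, int rebin,
                      bool use_att, bool use_rr) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int nv = angles.size();
  if (nx % rebin != 0 || nz % rebin != 0)
    stop("grid dims must be divisible by the rebin factor");
  const int nu = nx / rebin, nw = nz / rebin;
  const double dl_cm = voxel_mm / 10.0;
  const double cyc = 0.5 * (ny - 1);

  NumericVector out((size_t)nx * ny * nz);
  std::vector<double> rotM;
  if (use_att) rotM.resize((size_t)nx * ny * nz);
  std::vector<double> rotOut((size_t)nx * ny * nz);
  std::vector<double> q((size_t)nx * nz), bl((size_t)nx * nz),
      tmp((size_t)nx * nz), attline((size_t)nx * nz);

  for (int v = 0; v < nv; ++v) {
    double ca = std::cos(angles[v]), sa = std::sin(angles[v]);
    if (use_att) rotate_gather(REAL(mu), rotM.data(), nx, ny, nz, ca, sa);
    // adjoint of rebin: replicate
    const double *sv = REAL(sino) + (size_t)v * nu * nw;
    for (int iz = 0; iz < nz; ++iz)
      for (int ix = 0; ix < nx; ++ix)
        q[(size_t)iz * nx + ix] = sv[(size_t)(iz / rebin) * nu + (ix / rebin)];
    std::fill(attline.begin(), attline.end(), 0.0);
    std::fill(rotOut.begin(), rotOut.end(), 0.0);
    for (int iy = ny - 1; iy >= 0; --iy) {
      double dist = orbit_mm[v] - (iy - cyc) * voxel_mm;
      if (dist < 0) dist = 0;
      double sig = use_rr ? (sigma0 + slope * dist) / voxel_mm : 0.0;
      Kernel k = make_kernel(sig);
      blur_plane(q.data(), bl.data(), tmp.data(), nx, nz, k);
      for (int iz = 0; iz < nz; ++iz)
        for (int ix = 0; ix < nx; ++ix) {
          size_t pi = (size_t)iz * nx + ix;
          size_t vi = (size_t)iz * nx * ny + (size_t)iy * nx + ix;
          double w = 1.0;
          if (use_att) {
            double m = rotM[vi];
            w = std::exp(-(attline[pi] + 0.5 * m * dl_cm));
            attline[pi] += m * dl_cm;
          }
          rotOut[vi] = bl[pi] * w;
        }
    }
    rotate_gather(rotOut.data(), REAL(out), nx, ny, nz, ca, sa, true);
  }
  out.attr("dim") = dim;
  return out;
}

// Gaussian blur of each (u,v) plane of a [nu, nv, n] stack; sigma in bins.
// Used by the scatter simulator (kernel convolution model) and the planar
// point-source simulator. Edge-renormalised so a flat plane is preserved
// (the projector PSF path is NOT renormalised, keeping it self-adjoint).
// [[Rcpp::export(name = ".lq_blur_planes")]]
NumericVector lq_blur_planes(NumericVector arr, IntegerVector dim,
                             double sigma_bins) {
  const int nu = dim[0], nv = dim[1], np = dim[2];
  NumericVector out((size_t)nu * nv * np);
  Kernel k = make_kernel(sigma_bins);
  std::vector<double> tmp((size_t)nu * nv);
  for (int p = 0; p < np; ++p)
    blur_plane(REAL(arr) + (size_t)p * nu * nv, REAL(out) + (size_t)p * nu * nv,
               tmp.data(), nu, nv, k, true);
  out.attr("dim") = dim;
  return out;
}

// Fractional-fill rasterizer: per-voxel inside fraction of a solid by
// nsub^3 supersampling of candidate boundary voxels (interior voxels set to
// 1 directly). Supported kinds: "ellipsoid" (semi-axes rx, ry, rz; a sphere
// when equal) and "ecylinder" (z-aligned elliptical cylinder, semi-axes
// rx, ry, half-height rz). Coordinates are physical mm; the centre of voxel
// index i is origin + i*voxel.
// [[Rcpp::export(name = ".lq_rasterize")]]
NumericVector lq_rasterize(IntegerVector dim, double voxel_mm,
                           NumericVector origin, std::string kind,
                           NumericVector centre, NumericVector radii,
                           int nsub) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((size_t)nx * ny * nz);
  const double h = voxel_mm;
  const double rx = radii[0], ry = radii[1], rz = radii[2];
  const bool cyl = (kind == "ecylinder");
  int x0 = (int)std::floor((centre[0] - rx - origin[0]) / h) - 1;
  int x1 = (int)std::ceil((centre[0] + rx - origin[0]) / h) + 1;
  int y0 = (int)std::floor((centre[1] - ry - origin[1]) / h) - 1;
  int y1 = (int)std::ceil((centre[1] + ry - origin[1]) / h) + 1;
  int z0 = (int)std::floor((centre[2] - rz - origin[2]) / h) - 1;
  int z1 = (int)std::ceil((centre[2] + rz - origin[2]) / h) + 1;
  if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
  if (x1 >= nx) x1 = nx - 1; if (y1 >= ny) y1 = ny - 1;
  if (z1 >= nz) z1 = nz - 1;
  const double sub = 1.0 / nsub;
  double rmin = rx < ry ? rx : ry;
  if (!cyl && rz < rmin) rmin = rz;
  const double margin = 0.8661 * h / rmin; // > sqrt(3)/2 voxel diagonal
  for (int iz = z0; iz <= z1; ++iz) {
    double zc = origin[2] + iz * h - centre[2];
    for (int iy = y0; iy <= y1; ++iy) {
      double yc = origin[1] + iy * h - centre[1];
      for (int ix = x0; ix <= x1; ++ix) {
        double xc = origin[0] + ix * h - centre[0];
        double nrm; // normalised radial coordinate (1 on the surface)
        bool clearly_in, clearly_out;
        double px = xc / rx, py = yc / ry;
        if (cyl) {
          nrm = std::sqrt(px * px + py * py);
          double zd = std::fabs(zc);
          clearly_in = (nrm <= 1.0 - margin) && (zd + 0.5 * h <= rz);
          clearly_out = (nrm >= 1.0 + margin) || (zd - 0.5 * h >= rz);
        } else {
          double pz = zc / rz;
          nrm = std::sqrt(px * px + py * py + pz * pz);
          clearly_in = nrm <= 1.0 - margin;
          clearly_out = nrm >= 1.0 + margin;
        }
        size_t vi = (size_t)iz * nx * ny + (size_t)iy * nx + ix;
        if (clearly_out) continue;
        if (clearly_in) { out[vi] = 1.0; continue; }
        if (cyl) {
          // separable: exact z-interval overlap (flat caps align with the
          // grid and would otherwise bias midpoint supersampling), 2D
          // supersampling for the curved cross-section
          double fz = (std::min(zc + 0.5 * h, rz) -
                       std::max(zc - 0.5 * h, -rz)) / h;
          if (fz <= 0) continue;
          if (fz > 1) fz = 1;
          int cnt = 0;
          for (int a = 0; a < nsub; ++a) {
            double xs = (xc + (a + 0.5) * sub * h - 0.5 * h) / rx;
            for (int b = 0; b < nsub; ++b) {
              double ys = (yc + (b + 0.5) * sub * h - 0.5 * h) / ry;
              if (xs * xs + ys * ys <= 1.0) ++cnt;
            }
          }
          out[vi] = fz * (double)cnt / (nsub * nsub);
        } else {
          int cnt = 0;
          for (int a = 0; a < nsub; ++a) {
            double xs = (xc + (a + 0.5) * sub * h - 0.5 * h) / rx;
            for (int b = 0; b < nsub; ++b) {
              double ys = (yc + (b + 0.5) * sub * h - 0.5 * h) / ry;
              double p2 = xs * xs + ys * ys;
              for (int c = 0; c < nsub; ++c) {
                double zs = (zc + (c + 0.5) * sub * h - 0.5 * h) / rz;
                if (p2 + zs * zs <= 1.0) ++cnt;
              }
            }
          }
          out[vi] = (double)cnt / (nsub * nsub * nsub);
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}
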