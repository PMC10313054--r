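#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closest point on a single triangle (a,b,c) to p (Ericson, Real-Time
// Collision Detection, section 5.1.5). Writes result into out[3].
static inline double closest_on_tri(const double *p, const double *a,
                                    const double *b, const double *c,
                                    double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
  } else {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = (d1 - d3 != 0.0) ? d1 / (d1 - d3) : 0.0;
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
      } else {
        double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = (d2 - d6 != 0.0) ? d2 / (d2 - d6) : 0.0;
            for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
          } else {
            double va = d3*d6 - d5*d4;
            double dd = (d4 - d3) + (d5 - d6);
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0 && dd != 0.0) {
              double w = (d4 - d3) / dd;
              for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
            } else {
              double denom = va + vb + vc;
              double v = (denom != 0.0) ? vb / denom : 0.0;
              double w = (denom != 0.0) ? vc / denom : 0.0;
              for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return dx*dx + dy*dy + dz*dz;
}

// For each query point, the closest point on the triangle soup (V, F).
// Uses a per-triangle bounding-sphere reject against the current best to
// keep the brute-force scan cheap. F is 1-based.
// [[Rcpp::export(name = ".cppClosestOnMesh")]]
List cppClosestOnMesh(NumericMatrix Q, NumericMatrix V, IntegerMatrix F) {
  int nq = Q.nrow(), nf = F.nrow();
  NumericMatrix P(nq, 3);
  NumericVector D(nq);
  IntegerVector FI(nq);
  // precompute triangle centroids and bounding radii
  std::vector<double> cx(nf), cy(nf), cz(nf), br(nf);
  for (int f = 0; f < nf; ++f) {
    int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
    double mx = (V(ia,0)+V(ib,0)+V(ic,0))/3.0;
    double my = (V(ia,1)+V(ib,1)+V(ic,1))/3.0;
    double mz = (V(ia,2)+V(ib,2)+V(ic,2))/3.0;
    cx[f]=mx; cy[f]=my; cz[f]=mz;
    double r2 = 0.0;
    int idx[3] = {ia, ib, ic};
    for (int k = 0; k < 3; ++k) {
      double dx=V(idx[k],0)-mx, dy=V(idx[k],1)-my, dz=V(idx[k],2)-mz;
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 > r2) r2 = d2;
    }
    br[f] = std::sqrt(r2);
  }
  double p[3], a[3], b[3], c[3], out[3], best_out[3];
  for (int q = 0; q < nq; ++q) {
    p[0]=Q(q,0); p[1]=Q(q,1); p[2]=Q(q,2);
    double best = R_PosInf; int bestf = -1;
    double bestd = R_PosInf; // sqrt of best
    // seed with the nearest-centroid triangle so the sphere reject bites
    {
      double bc = R_PosInf; int bf = 0;
      for (int f = 0; f < nf; ++f) {
        double dx=p[0]-cx[f], dy=p[1]-cy[f], dz=p[2]-cz[f];
        double d2 = dx*dx+dy*dy+dz*dz;
        if (d2 < bc) { bc = d2; bf = f; }
      }
      int ia = F(bf,0)-1, ib = F(bf,1)-1, ic = F(bf,2)-1;
      for (int i = 0; i < 3; ++i) { a[i]=V(ia,i); b[i]=V(ib,i); c[i]=V(ic,i); }
      double d2 = closest_on_tri(p, a, b, c, out);
      best = d2; bestf = bf; bestd = std::sqrt(d2);
      best_out[0]=out[0]; best_out[1]=out[1]; best_out[2]=out[2];
    }
    for (int f = 0; f < nf; ++f) {
      double dx=p[0]-cx[f], dy=p[1]-cy[f], dz=p[2]-cz[f];
      double dc = std::sqrt(dx*dx+dy*dy+dz*dz) - br[f];
      if (dc > bestd) continue;
      int ia = F(f,0)-1, ib = F(f,1)-1, ic = F(f,2)-1;
      for (int i = 0; i < 3; ++i) { a[i]=V(ia,i); b[i]=V(ib,i); c[i]=V(ic,i); }
      double d2 = closest_on_tri(p, a, b, c, out);
      if (d2 < best) {
        best = d2; bestf = f; bestd = std::sqrt(d2);
        best_out[0]=out[0]; best_out[1]=out[1]; best_out[2]=out[2];
      }
    }
    P(q,0)=best_out[0]; P(q,1)=best_out[1]; P(q,2)=best_out[2];
    D[q] = bestd; FI[q] = bestf + 1;
  }
  return List::create(_["point"] = P, _["distance"] = D, _["face"] = FI);
}

// Nearest-neighbour indices from each row of Q to rows of P (1-based).
// [[Rcpp::export(name = ".cppNearestPoint")]]
List cppNearestPoint(NumericMatrix Q, NumericMatrix P) {
  int nq = Q.nrow(), np = P.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf; int bi = 0;
    double x = Q(q,0), y = Q(q,1), z = Q(q,2);
    for (int p = 0; p < np; ++p) {
      double dx=x-P(p,0), dy=y-P(p,1), dz=z-P(p,2);
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < best) { best = d2; bi = p; }
    }
    idx[q] = bi + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
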