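#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive candidate search over the CHNOSP(Cl,Fe) composition grid.
//
// For each target neutral mass, loops over every admissible heteroatom
// combination (N,S,P,Cl,Fe rows of `het`, prohibition rules already applied)
// and oxygen count, then completes carbon and hydrogen in closed form: for a
// fixed residual mass r = m - m(het) - O*mO and carbon count C, the only
// hydrogen count that can fall inside a sub-ppm window is round((r - C*mC)/mH)
// because the window (< 0.001 Da) is far narrower than one hydrogen mass.
// This is provably equivalent to the full 8-deep nested enumeration and is
// checked against a brute-force oracle in the test suite.
//
// [[Rcpp::export]]
DataFrame enumerate_grid_cpp(NumericVector masses, double tol_ppm,
                             IntegerMatrix het, NumericVector het_mass,
                             int c_min, int c_max, int h_min, int h_max,
                             int o_min, int o_max,
                             double mC, double mH, double mO) {
  std::vector<int> peak, vC, vH, vN, vO, vS, vP, vCl, vFe;
  std::vector<double> vmass, verr;

  const int nhet = het.nrow();
  for (int ip = 0; ip < masses.size(); ++ip) {
    const double m = masses[ip];
    const double tol = m * tol_ppm * 1e-6;
    for (int k = 0; k < nhet; ++k) {
      const double rem0 = m - het_mass[k];
      // smallest possible candidate with this het block
      if (rem0 < c_min * mC + h_min * mH + o_min * mO - tol) continue;
      const int o_hi = std::min((double)o_max,
                                std::floor((rem0 - c_min * mC - h_min * mH + tol) / mO));
      for (int O = o_min; O <= o_hi; ++O) {
        const double rem = rem0 - O * mO;
        int c_lo = (int)std::ceil((rem - h_max * mH - tol) / mC);
        int c_hi2 = (int)std::floor((rem - h_min * mH + tol) / mC);
        if (c_lo < c_min) c_lo = c_min;
        if (c_hi2 > c_max) c_hi2 = c_max;
        for (int C = c_lo; C <= c_hi2; ++C) {
          const double hf = (rem - C * mC) / mH;
          const int H = (int)std::lround(hf);
          if (H < h_min || H > h_max) continue;
          const double cand = het_mass[k] + O * mO + C * mC + H * mH;
          const double err_ppm = (cand - m) / m * 1e6;
          if (std::fabs(err_ppm) < tol_ppm) {
            peak.push_back(ip + 1);
            vC.push_back(C); vH.push_back(H);
            vN.push_back(het(k, 0)); vO.push_back(O); vS.push_back(het(k, 1));
            vP.push_back(het(k, 2)); vCl.push_back(het(k, 3)); vFe.push_back(het(k, 4));
            vmass.push_back(cand); verr.push_back(err_ppm);
          }
        }
      }
    }
  }
  return DataFrame::create(
    _["peak"] = wrap(peak),
    _["C"] = wrap(vC), _["H"] = wrap(vH), _["N"] = wrap(vN),
    _["O"] = wrap(vO), _["S"] = wrap(vS), _["P"] = wrap(vP),
    _["Cl"] = wrap(vCl), _["Fe"] = wrap(vFe),
    _["neutral_mass"] = wrap(vmass), _["error_ppm"] = wrap(verr));
}
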