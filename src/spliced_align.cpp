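#include <Rcpp.h>
using namespace Rcpp;

// Local spliced-alignment DP between a protein query and a DNA target.
//
// State (i, j): i protein residues and j DNA bases consumed.  Moves:
//   codon match : (i-1, j-3) -> (i, j), scored smat(i-1, codon at j-3)
//   intron      : (i, j')    -> (i, j), any j - j' >= min_intron, flat penalty
//   protein gap : (i-1, j)   -> (i, j), affine (open/extend)
//   DNA codon gap: (i, j-3)  -> (i, j), affine (open/extend)
// Local semantics: every cell may restart at 0; the reported score is the
// global maximum over all cells.  Affine gaps open from the cell optimum and
// extend within their own state, the standard Gotoh formulation.
//
// smat: N x 64 score of residue i vs codon index (A=0,C=1,G=2,T=3;
//       idx = 16*b1 + 4*b2 + b3); stop-codon columns are pre-filled by the
//       caller.  cod[j] = codon index starting at 0-based j, or -1.
//
// Alongside scores we carry intron and matched-residue counts along the
// optimal path (ties broken by fixed move order: match, intron, protein gap,
// DNA gap, restart) so the caller can report n_introns / aligned_fraction.
//
// Memory is two rolling rows; time O(N * M) via a per-row prefix maximum for
// the intron move.

// [[Rcpp::export]]
List spliced_align_core(NumericMatrix smat, IntegerVector cod,
                        double gap_open, double gap_ext,
                        double intron_pen, int min_intron) {
  const int N = smat.nrow();      // protein length
  const int M = cod.size();       // DNA length (nt)
  const int W = M + 1;

  // previous / current row buffers
  std::vector<double> Vp(W, 0.0), Vc(W, 0.0);     // cell optimum
  std::vector<double> Pp(W), Pc(W);               // protein-gap state
  std::vector<int> VpI(W, 0), VcI(W, 0), VpM(W, 0), VcM(W, 0);
  std::vector<int> PpI(W, 0), PcI(W, 0), PpM(W, 0), PcM(W, 0);
  const double NEG = -1e100;
  std::fill(Pp.begin(), Pp.end(), NEG);

  double best = 0.0; int bestI = 0, bestM = 0;

  for (int i = 1; i <= N; ++i) {
    // same-row DNA-gap state and intron prefix maximum
    std::vector<double> D(W, NEG);  std::vector<int> DI(W, 0), DM(W, 0);
    double pref = NEG; int prefI = 0, prefM = 0;  // max over Vc[0..j-min_intron]
    Vc[0] = 0.0; VcI[0] = 0; VcM[0] = 0;
    Pc[0] = std::max(Vp[0] + gap_open, Pp[0] + gap_ext);
    if (Vp[0] + gap_open >= Pp[0] + gap_ext) { PcI[0] = VpI[0]; PcM[0] = VpM[0]; }
    else { PcI[0] = PpI[0]; PcM[0] = PpM[0]; }

    for (int j = 1; j <= M; ++j) {
      // advance intron prefix max to cover Vc[j - min_intron]
      if (j - min_intron >= 0) {
        int jj = j - min_intron;
        if (Vc[jj] > pref) { pref = Vc[jj]; prefI = VcI[jj]; prefM = VcM[jj]; }
      }
      // candidate moves
      double h = NEG; int hI = 0, hM = 0;
      if (j >= 3) {
        int c = cod[j - 3];
        if (c >= 0) {
          h = Vp[j - 3] + smat(i - 1, c);
          hI = VpI[j - 3]; hM = VpM[j - 3] + 1;
        }
      }
      double intr = NEG; int inI = 0, inM = 0;
      if (pref > NEG / 2) { intr = pref + intron_pen; inI = prefI + 1; inM = prefM; }

      double popen = Vp[j] + gap_open, pext = Pp[j] + gap_ext;
      if (popen >= pext) { Pc[j] = popen; PcI[j] = VpI[j]; PcM[j] = VpM[j]; }
      else { Pc[j] = pext; PcI[j] = PpI[j]; PcM[j] = PpM[j]; }

      if (j >= 3) {
        double dopen = Vc[j - 3] + gap_open, dext = D[j - 3] + gap_ext;
        if (dopen >= dext) { D[j] = dopen; DI[j] = VcI[j - 3]; DM[j] = VcM[j - 3]; }
        else { D[j] = dext; DI[j] = DI[j - 3]; DM[j] = DM[j - 3]; }
      }

      // cell optimum, fixed tie order
      double v = h; int vI = hI, vM = hM;
      if (intr > v) { v = intr; vI = inI; vM = inM; }
      if (Pc[j] > v) { v = Pc[j]; vI = PcI[j]; vM = PcM[j]; }
      if (D[j] > v)  { v = D[j];  vI = DI[j];  vM = DM[j]; }
      if (v < 0.0) { v = 0.0; vI = 0; vM = 0; }
      Vc[j] = v; VcI[j] = vI; VcM[j] = vM;

      if (v > best) { best = v; bestI = vI; bestM = vM; }
    }
    std::swap(Vp, Vc); std::swap(VpI, VcI); std::swap(VpM, VcM);
    std::swap(Pp, Pc); std::swap(PpI, PcI); std::swap(PpM, PcM);
    std::fill(Vc.begin(), Vc.end(), 0.0);
  }

  return List::create(_["score"] = best,
                      _["n_introns"] = bestI,
                      _["n_matched"] = bestM);
}
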