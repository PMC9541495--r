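# Independent brute-force oracle for the 1:1 bound-ligand equilibrium:
# root of K*B - (X - B)(FL - B) = 0 on [0, min(X, FL)], found by uniroot
# at near machine tolerance. Deliberately does not call the package's
# closed-form solution.
oracle_bound_1to1 <- function(K, X, FL) {
  if (X == 0 || FL == 0) return(0)
  f <- function(B) K * B - (X - B) * (FL - B)
  top <- min(X, FL)
  if (f(top) < 0) return(top)  # K == 0 edge: all of the limiting species
  stats::uniroot(f, c(0, top), tol = top * 1e-15)$root
}

# study peptide sequences in the package's notation (acetyl/amide chemistry)
tbl1 <- list(
  hDMX_361_374  = list(seq = "Ac-DCRRTIpSAPVVRPK-NH2", offset = 361),
  hDMX_335_349  = list(seq = "Ac-SKLTHSLpSTSDITAI-NH2", offset = 335),
  hDM2_180_192  = list(seq = "Ac-QRKRHKpSDSISLS-NH2", offset = 180),
  hDM2_160_171  = list(seq = "Ac-SRRRAIpSETEEN-NH2", offset = 160),
  hDMX_335_373  = list(
    seq = "Ac-SKLTHSLpSTSDITAIPEKENEGNDVPDCRRTIpSAPVVRP-NH2",
    offset = 335)
)
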