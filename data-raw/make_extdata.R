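# Generates the packaged synthetic extinction tables (450-650 nm, 1 nm grid).
wl <- 450:650

hbo2 <- 1.00 * exp(-(wl - 450) / 22) +
  0.38 * exp(-((wl - 542) / 10)^2) +
  0.36 * exp(-((wl - 577) / 9)^2) + 0.004
hb <- 0.85 * exp(-(wl - 450) / 28) +
  0.60 * exp(-((wl - 555) / 23)^2) +
  0.08 * exp(-((wl - 600) / 55)^2) + 0.010
fat <- 0.95 / (1 + exp((wl - 505) / 12)) +
  0.10 * exp(-((wl - 470) / 35)^2) + 0.002

# common scale so relative concentrations are comparable across chromophores
s <- max(hbo2, hb)
hbo2 <- hbo2 / s; hb <- hb / s; fat <- fat / max(fat)

w <- function(x, f) write.table(
  data.frame(wavelength_nm = wl, epsilon = signif(x, 6)),
  file.path("/root/pkg/inst/extdata", f),
  sep = "\t", row.names = FALSE, quote = FALSE)
w(hbo2, "extinction_hbo2_synthetic.tsv")
w(hb,   "extinction_hb_synthetic.tsv")
w(fat,  "extinction_fat_synthetic.tsv")

# sanity: Hb > HbO2 in the red (SO2 sensitivity), conditioning of the 8-band design
stopifnot(all(hb[wl >= 610] > hbo2[wl >= 610]))
centres <- c(470, 500, 520, 546, 560, 577, 600, 645)
Tm <- sapply(centres, function(cc) exp(-4 * log(2) * (wl - cc)^2 / 20^2))
bc <- function(e) colSums(e * Tm) / colSums(Tm)
X <- cbind(bc(hbo2), bc(hb), bc(fat), 1)
cat("kappa =", kappa(X, exact = TRUE), " rank =", qr(X)$rank, "\n")
print(round(X, 4))
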