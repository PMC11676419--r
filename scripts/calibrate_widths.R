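#!/usr/bin/env Rscript
# Width calibration for the default flagship configuration.
#
# The published model reports its parameter budget (total 13,662,913 =
# trainable 13,649,473 + non-trainable 13,440) but not the layer widths.
# Under the package's topology the non-trainable count equals twice the sum
# of batch-normalized channel widths, which pins
#     stem_width + 52 * dilated_channels + 54 * growth = 6720,
# and the trainable count is then an exact integer function of
# (stem_width S, dilated_channels D, growth g, d_ff F), linear in F. This
# script enumerates all (D, g) with the head count dividing the attention
# width, solves for the integer F that matches the trainable count exactly,
# and picks the solution with the smallest stem width: a wide stem at full
# resolution is the most expensive and least conventional place to spend
# parameters, so the narrowest stem is the most plausible configuration.
# The chosen configuration is frozen as model_config()'s defaults and in
# inst/config/default.yaml; build_model() is used to verify the triple.
#
# Fixed by design: L = 4 dense layers, compression theta = 0.5, 3 dilated
# convs (rates 2/4/8), patch schedule (1, 2, 4), d_model = channel width of
# each decoder concatenation (constant 3K/2, K = D + 4g). The head count
# does not affect parameter counts; the default is the largest count <= 4
# dividing d_model (3 for the chosen d_model = 294).

TARGET_TRAIN <- 13649473
TARGET_NONTRAIN <- 13440
SUM_BN <- TARGET_NONTRAIN / 2   # 6720

flagship_trainable <- function(S, D, g, F) {
  L <- 4
  K <- D + L * g          # every DDB output width
  Kh <- K %/% 2           # transition / upsample output width
  c3 <- Kh + K            # decoder concatenation width = attention d_model
  ddb <- function(cin) {
    dil <- 9 * cin * D + D + 2 * D +      # conv + bias + BN (gamma, beta)
      2 * (9 * D * D + D + 2 * D)
    Cj <- D + (0:(L - 1)) * g
    den <- sum(2 * Cj) + sum(9 * Cj * g + g)
    dil + den
  }
  trans <- 2 * K + (K * Kh + Kh) + (9 * Kh * Kh + Kh)
  upsm <- K * Kh + Kh
  tf <- function(p) {
    td <- c3 * p * p
    (td * c3 + c3) +                       # patch embedding
      (4 * c3 * c3 + 4 * c3) +             # MHSA projections
      2 * (2 * c3) +                       # two layer norms
      (c3 * F + F + F * c3 + c3) +         # FFN
      (c3 * td + td)                       # unembedding
  }
  stemp <- 9 * S + S + 2 * S
  enc <- ddb(S) + ddb(Kh) + ddb(Kh)
  cen <- ddb(Kh)
  dec <- 3 * ddb(c3)
  head <- K + 1
  stemp + enc + 3 * trans + cen + 3 * upsm + dec +
    tf(1) + tf(2) + tf(4) + head
}

cand <- list()
for (D in 8:127) {
  for (g in 4:((SUM_BN - 52 * D - 8) %/% 54)) {
    K <- D + 4 * g
    if (K %% 2 != 0) next                 # theta = 1/2 must be exact
    S <- SUM_BN - 52 * D - 54 * g
    if (S < 8 || S > 1024) next
    t0 <- flagship_trainable(S, D, g, 0)
    coefF <- flagship_trainable(S, D, g, 1) - t0
    rem <- TARGET_TRAIN - t0
    if (rem <= 0 || rem %% coefF != 0) next
    F <- rem %/% coefF
    c3 <- 3 * K / 2
    if (F < 16 || F > 16 * c3) next
    cand[[length(cand) + 1]] <- data.frame(S = S, D = D, g = g, F = F,
                                           K = K, d_model = c3,
                                           ratio = F / c3)
  }
}
cand <- do.call(rbind, cand)
stopifnot(nrow(cand) >= 1)
cand <- cand[order(cand$S), ]
cat("exact-match candidates:\n")
print(cand, row.names = FALSE)
best <- cand[1, ]
cat(sprintf("\nchosen: stem_width=%d dilated_channels=%d growth=%d d_ff=%d (d_model=%d)\n",
            best$S, best$D, best$g, best$F, best$d_model))

# verify against the real builder
suppressMessages(library(strokeseg))
cfg <- model_config(stem_width = best$S, growth = best$g,
                    dilated_channels = best$D, d_ff = best$F)
pc <- count_parameters(build_model(cfg, seed = 1))
print(pc)
stopifnot(pc$trainable == TARGET_TRAIN, pc$non_trainable == TARGET_NONTRAIN)
cat("verified against build_model()\n")
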