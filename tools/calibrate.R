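# Calibration of the shipped constants in inst/extdata/calibration.yaml:
#   - gait-score linear-model coefficients (features -> severity, least
#     squares on the default synthetic cohort, ground-truth labels)
#   - dyskinesia severity scale (deg/s band RMS -> device scale, anchored so
#     the AIMS>4 boundary of the generator sits at the 1.66 operating point)
#   - bradykinesia normative speed (5th percentile of control event peaks)
# Run from the package root:  Rscript tools/calibrate.R

suppressMessages(pkgload::load_all(".", quiet = TRUE))

plan <- simulateCohort(seed = 42)
cfg <- defaultConfig()

gaitRows <- list(); dyskRows <- list(); ctrlPeaks <- c()
for (i in seq_len(nrow(plan$subjects))) {
  for (d in seq_len(plan$days)) {
    sim <- cohortRecording(plan, i, d)
    lab <- sim$truth$windows$label
    post <- matrix(0, length(lab), 5, dimnames = list(NULL, pdmotor:::ACTIVITY_CLASSES))
    post[cbind(seq_along(lab), match(lab, pdmotor:::ACTIVITY_CLASSES))] <- 1
    sy <- detectSymptoms(sim$recording, lab, post, cfg)
    tb <- pdmotor:::simTruthBins(plan$profiles[[i]], plan$schedules[[i]][[d]])
    gr <- sy$gaitRegions
    if (!is.null(gr)) {
      gr$severity <- tb$gait_severity[match(floor(gr$start_s / 1800) + 1, tb$bin)]
      gaitRows[[length(gaitRows) + 1]] <- gr
    }
    dr <- sy$dyskRegions
    dr <- dr[!dr$excluded & dr$dyskinetic, ]
    if (nrow(dr)) {
      dr$dysk_eff <- tb$dysk_eff[match(floor(dr$start_s / 1800) + 1, tb$bin)]
      dyskRows[[length(dyskRows) + 1]] <- dr
    }
    if (plan$subjects$isControl[i])
      ctrlPeaks <- c(ctrlPeaks, sy$movements$peak_dps)
    message(plan$subjects$subject[i], " day ", d, " done")
  }
}

gaitDf <- do.call(rbind, gaitRows)
cat("gait regions:", nrow(gaitDf), "\n")
gm <- fitGaitModel(gaitDf)
print(unlist(gm$coef))

dyskDf <- do.call(rbind, dyskRows)
dyskDf <- dyskDf[dyskDf$dysk_eff > 0, ]
cat("dyskinetic regions:", nrow(dyskDf), "\n")
# band RMS grows ~linearly with the generator gain: rms = c * dysk_eff
cc <- mean(dyskDf$band_rms / dyskDf$dysk_eff)
# the annotation inverse map puts the AIMS>4 boundary at dysk_eff ~ 8.2;
# anchor the device scale so that boundary maps onto the 1.66 threshold
dyskScale <- 1.66 / (cc * 8.2)
cat("rms per unit gain:", cc, " -> dysk scale:", dyskScale, "\n")

cat("control movement events:", length(ctrlPeaks), "\n")
norm <- fitNormative(ctrlPeaks)
cat("normative 5th percentile:", norm, "\n")

out <- list(gait_model = gm, dysk_scale = dyskScale,
            brady_normative_dps = norm)
yaml::write_yaml(out, "inst/extdata/calibration.yaml", precision = 15)
cat("written inst/extdata/calibration.yaml\n")
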