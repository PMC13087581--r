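# Shared fixtures, built in code.

# a GrowthCurve without going through the pipeline
makeCurve <- function(values, times = seq_along(values) - 1,
                      construct = "A", medium = "citrulline", bio = 1L,
                      stage = character()) {
  new("GrowthCurve",
      curveId = sprintf("%s/%s/bio%d", construct, medium, bio),
      construct = construct, medium = medium, bioReplicate = bio,
      techReplicate = NA_integer_, times = as.numeric(times),
      values = as.numeric(values), stage = stage)
}

makeTrace <- function(values, times = (seq_along(values) - 1) / 6,
                      well = "A1", kind = "RNU") {
  new("WellTimeseries", wellId = well, times = as.numeric(times),
      values = as.numeric(values), signalKind = kind)
}

logisticVals <- function(K, N0, r, t) K / (1 + ((K - N0) / N0) * exp(-r * t))

# write a long timeseries CSV from a named list of value vectors on one grid
writeTimeseriesCsv <- function(wellValues, times, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(names(wellValues), function(w)
    data.frame(well = w, time_h = times, value = wellValues[[w]])))
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Independent brute-force Mann-Whitney oracle: literally enumerates all
# C(na+nb, na) assignments of the pooled ranks to group a. Tie-free only.
bruteMannWhitney <- function(x, y) {
  na <- length(x); nb <- length(y)
  rk <- rank(c(x, y))
  Ra <- sum(rk[seq_len(na)])
  Ua <- Ra - na * (na + 1) / 2
  U <- min(Ua, na * nb - Ua)
  sets <- utils::combn(na + nb, na)
  allU <- apply(sets, 2, function(s) sum(s) - na * (na + 1) / 2)
  p <- min(1, 2 * mean(allU <= U))
  list(U = U, p = p)
}

# layout data.frame row helpers
layoutRow <- function(well, construct = NA, medium = "citrulline",
                      bio = NA, tech = NA, role = "sample") {
  data.frame(well = well, construct = as.character(construct),
             medium = medium, bio_replicate = as.integer(bio),
             tech_replicate = as.integer(tech), role = role,
             stringsAsFactors = FALSE)
}
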