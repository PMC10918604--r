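# displacement (km) from release point at a given snapshot, alive particles only
.displacements <- function(ts, pld) {
  snap <- snapshotPositions(ts, pld)
  ok <- snap$alive & !is.na(snap$lon)
  if (!any(ok)) return(numeric(0))
  haversineKm(ts@release$lon, ts@release$lat, snap$lon[ok], snap$lat[ok])
}

.trajYears <- function(trajectories)
  unique(vapply(trajectories, function(ts) ts@release$year, character(1)))

.trajFor <- function(trajectories, site, year) {
  for (ts in trajectories)
    if (ts@release$site == site && ts@release$year == year) return(ts)
  NULL
}

#' Buffer-zone connectivity matrix
#'
#' \code{P[i, j]} = proportion of site-i particles credited to site j's
#' source zone (great-circle disc of \code{radiusKm}). Default convention:
#' membership is judged at the \code{pld}-day snapshot among particles still
#' alive then, and the denominator is the number alive at \code{pld} days.
#' \code{convention = "any_time"} instead credits a particle to every zone it
#' entered at any stored snapshot up to \code{pld} (same denominator).
#' Yearly matrices and their across-year elementwise mean are returned.
#'
#' @param trajectories list of \linkS4class{TrajectorySet} (a campaign).
#' @param sites site table (\code{site, lon, lat}).
#' @param pld pelagic larval duration in days; a stored snapshot.
#' @param radiusKm buffer-zone radius (default 20).
#' @param convention \code{"snapshot"} or \code{"any_time"}.
#' @return a \linkS4class{ConnectivityMatrix}.
#' @export
dispersalMatrix <- function(trajectories, sites, pld, radiusKm = 20,
                            convention = c("snapshot", "any_time")) {
  convention <- match.arg(convention)
  years <- .trajYears(trajectories)
  ns <- nrow(sites)
  yearly <- list()
  for (y in years) {
    P <- matrix(NA_real_, ns, ns, dimnames = list(sites$site, sites$site))
    for (i in seq_len(ns)) {
      ts <- .trajFor(trajectories, sites$site[i], y)
      if (is.null(ts)) next
      snap <- snapshotPositions(ts, pld)
      aliveIdx <- which(snap$alive & !is.na(snap$lon))
      if (length(aliveIdx) == 0L) {
        warning("no particles alive at PLD ", pld, " for ",
                sites$site[i], " ", y, "; row is NaN")
        next
      }
      if (convention == "snapshot") {
        for (j in seq_len(ns)) {
          d <- haversineKm(snap$lon[aliveIdx], snap$lat[aliveIdx],
                           sites$lon[j], sites$lat[j])
          P[i, j] <- sum(d <= radiusKm) / length(aliveIdx)
        }
      } else {
        kMax <- which(abs(ts@times - pld) < 1e-9)
        entered <- matrix(FALSE, length(aliveIdx), ns)
        for (k in seq_len(kMax)) {
          px <- ts@lon[aliveIdx, k]; py <- ts@lat[aliveIdx, k]
          for (j in seq_len(ns)) {
            d <- haversineKm(px, py, sites$lon[j], sites$lat[j])
            entered[, j] <- entered[, j] | (!is.na(d) & d <= radiusKm)
          }
        }
        P[i, ] <- colSums(entered) / length(aliveIdx)
      }
    }
    yearly[[as.character(y)]] <- P
  }
  arr <- simplify2array(yearly)
  meanP <- apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  new("ConnectivityMatrix", sites = sites$site, yearly = yearly,
      mean = meanP, pld = pld, radiusKm = radiusKm, convention = convention)
}

#' Per-site dispersal summary
#'
#' One row per site: mean percentage of released particles remaining in the
#' simulation at \code{pld} days (averaged over years, all-dead years count
#' as 0\%), mean percentage of surviving particles inside the release site's
#' own source zone, mean displacement (mean over particles within a year,
#' then over years with survivors) and maximum displacement over all
#' particles and years. Displacement is the great-circle distance from the
#' release point to the \code{pld}-day position.
#'
#' @inheritParams dispersalMatrix
#' @return data.frame \code{site, pld, pctRemaining, pctSourceZone,
#'   meanDispKm, maxDispKm}.
#' @export
dispersalSummary <- function(trajectories, sites, pld, radiusKm = 20) {
  years <- .trajYears(trajectories)
  out <- data.frame(site = sites$site, pld = pld, pctRemaining = NA_real_,
                    pctSourceZone = NA_real_, meanDispKm = NA_real_,
                    maxDispKm = NA_real_)
  for (i in seq_len(nrow(sites))) {
    remain <- src <- mds <- maxs <- numeric()
    for (y in years) {
      ts <- .trajFor(trajectories, sites$site[i], y)
      if (is.null(ts)) next
      snap <- snapshotPositions(ts, pld)
      aliveIdx <- which(snap$alive & !is.na(snap$lon))
      remain <- c(remain, 100 * length(aliveIdx) / nrow(ts@lon))
      if (length(aliveIdx) == 0L) next
      d <- haversineKm(ts@release$lon, ts@release$lat,
                       snap$lon[aliveIdx], snap$lat[aliveIdx])
      src <- c(src, 100 * mean(d <= radiusKm))
      mds <- c(mds, mean(d))
      maxs <- c(maxs, max(d))
    }
    out$pctRemaining[i] <- if (length(remain)) mean(remain) else NA_real_
    out$pctSourceZone[i] <- if (length(src)) mean(src) else NA_real_
    out$meanDispKm[i] <- if (length(mds)) mean(mds) else NA_real_
    out$maxDispKm[i] <- if (length(maxs)) max(maxs) else NA_real_
  }
  out
}

#' Interannual dispersal variation report
#'
#' Per site: the year-to-year range of mean displacement, the ratio of the
#' overall maximum to the overall mean displacement, and rare long-distance
#' dispersal years — years whose maximum displacement exceeds \code{factor}
#' times the mean of the other years' maximum displacements (leave-one-out,
#' so a single anomalous year does not inflate its own baseline).
#'
#' @inheritParams dispersalMatrix
#' @param factor flagging threshold (default 2).
#' @return list with \code{perSiteYear} (site, year, meanDispKm, maxDispKm),
#'   \code{perSite} (site, rangeMeanKm, ratioMaxMean, rareYears) and
#'   \code{flagged} (site, year rows for rare events). With a single year the
#'   variation fields are \code{NA}.
#' @export
interannualReport <- function(trajectories, sites, pld, factor = 2) {
  years <- .trajYears(trajectories)
  psy <- expand.grid(site = sites$site, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  psy$meanDispKm <- NA_real_; psy$maxDispKm <- NA_real_
  for (r in seq_len(nrow(psy))) {
    ts <- .trajFor(trajectories, psy$site[r], psy$year[r])
    if (is.null(ts)) next
    d <- .displacements(ts, pld)
    if (length(d)) { psy$meanDispKm[r] <- mean(d); psy$maxDispKm[r] <- max(d) }
  }
  perSite <- data.frame(site = sites$site, rangeMeanKm = NA_real_,
                        ratioMaxMean = NA_real_, rareYears = "",
                        stringsAsFactors = FALSE)
  flagged <- psy[0, c("site", "year")]
  multiYear <- length(years) >= 2
  for (i in seq_len(nrow(sites))) {
    rows <- psy[psy$site == sites$site[i] & !is.na(psy$meanDispKm), ]
    if (nrow(rows) == 0L) next
    overallMean <- mean(rows$meanDispKm)
    perSite$ratioMaxMean[i] <- if (overallMean > 0)
      max(rows$maxDispKm) / overallMean else NA_real_
    if (multiYear && nrow(rows) >= 2) {
      perSite$rangeMeanKm[i] <- diff(range(rows$meanDispKm))
      looBase <- vapply(seq_len(nrow(rows)),
                        function(k) mean(rows$maxDispKm[-k]), numeric(1))
      rare <- rows$year[rows$maxDispKm > factor * looBase]
      if (length(rare)) {
        perSite$rareYears[i] <- paste(rare, collapse = ",")
        flagged <- rbind(flagged, data.frame(site = sites$site[i], year = rare))
      }
    }
  }
  list(perSiteYear = psy, perSite = perSite, flagged = flagged,
       factor = factor, note = if (!multiYear) "single year: variation not applicable" else NULL)
}
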