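## Shared fixtures built in code.

## Two-node seasonal swap: north in summer, south in winter.
twoNodeNet <- function(width = 0.26, amplitude = 5, m = 48L) {
    MigrationNetwork(
        nodes = data.frame(id = 1:2, label = c("north", "south"),
                           lon = c(10, 15), lat = c(55, 30)),
        links = data.frame(from = c(1, 2), to = c(2, 1),
                           phase = c(4.58, 1.57), width = width,
                           amplitude = amplitude),
        m = m)
}

## Minimal fix table builder (Movebank-internal representation).
makeFixes <- function(id, dates, lon, lat, accuracy = 10,
                      hour = 12) {
    data.frame(id = id,
               timestamp = as.POSIXct(paste(dates,
                                            sprintf("%02d:00:00", hour)),
                                      tz = "UTC"),
               lon = lon, lat = lat, accuracy = accuracy,
               stringsAsFactors = FALSE)
}
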