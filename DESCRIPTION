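Package: pulsebp
Title: Cuffless Blood Pressure Estimation from Pulse Transit Time and
    PPG Intensity Ratio
Version: 0.1.0
Authors@R:
    person("pulsebp", "maintainers", email = "pulsebp@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for cuffless blood-pressure estimation from
    two-site arterial pulse waves and a photoplethysmography (PPG) channel.
    Computes pulse transit time (PTT) and pulse wave velocity (PWV) by
    dynamic-threshold beat detection on FIR band-pass filtered signals,
    estimates arterial diameter excursion from the PPG intensity ratio (PIR)
    via Beer-Lambert optics, and estimates systolic, diastolic and mean
    arterial pressure with both a log-PTT regression model and a
    hemodynamic P-beta model built on the Moens-Korteweg relation.
    Includes a physics-based synthetic signal generator (piezoelectric
    sensor chamber, analog front end, Beer-Lambert PPG optics) providing
    ground-truth cohorts, plus Bland-Altman and ISO 81060-2 agreement
    statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
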