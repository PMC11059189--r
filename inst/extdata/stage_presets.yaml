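# Stage preset library for the synthetic contact generator.
# fUltra: target fraction of intra-chromosomal contacts >= 10 Mb,
#   calibrated to published per-cell-type values (granule S1-S5 fractions
#   interpolated linearly between the printed S1 and S5 endpoints).
# alpha: short-range power-law slope; fInter: inter-chromosomal fraction;
# rho: same-compartment preference; drift: compartment shift applied to
# designated dynamic bins at this stage; hubChroms/hubWeight: elevated
# inter-chromosomal pair weights among the hub chromosome set.
presets:
  - name: human-S1
    species: human
    fUltra: 0.19
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: -0.15
    hubWeight: 1.0
  - name: human-S2
    species: human
    fUltra: 0.225
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: -0.075
    hubChroms: [chr1, chr9, chr11, chr14, chr15, chr16, chr17, chr21, chr22]
    hubWeight: 1.25
  - name: human-S3
    species: human
    fUltra: 0.26
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
    hubChroms: [chr1, chr9, chr11, chr14, chr15, chr16, chr17, chr21, chr22]
    hubWeight: 1.5
  - name: human-S4
    species: human
    fUltra: 0.295
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.075
    hubChroms: [chr1, chr9, chr11, chr14, chr15, chr16, chr17, chr21, chr22]
    hubWeight: 1.75
  - name: human-S5
    species: human
    fUltra: 0.33
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.15
    hubChroms: [chr1, chr9, chr11, chr14, chr15, chr16, chr17, chr21, chr22]
    hubWeight: 2.0
  - name: mouse-S1
    species: mouse
    fUltra: 0.19
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: -0.15
    hubWeight: 1.0
  - name: mouse-S2
    species: mouse
    fUltra: 0.2275
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: -0.075
    hubChroms: [chr7, chr4, chr5, chr11, chr17, chr19]
    hubWeight: 1.25
  - name: mouse-S3
    species: mouse
    fUltra: 0.265
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
    hubChroms: [chr7, chr4, chr5, chr11, chr17, chr19]
    hubWeight: 1.5
  - name: mouse-S4
    species: mouse
    fUltra: 0.3025
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.075
    hubChroms: [chr7, chr4, chr5, chr11, chr17, chr19]
    hubWeight: 1.75
  - name: mouse-S5
    species: mouse
    fUltra: 0.34
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.15
    hubChroms: [chr7, chr4, chr5, chr11, chr17, chr19]
    hubWeight: 2.0
  - name: human-forebrain-fetal
    species: human
    fUltra: 0.15
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: human-forebrain-mature
    species: human
    fUltra: 0.16
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: mouse-forebrain-immature
    species: mouse
    fUltra: 0.11
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: mouse-forebrain-mature
    species: mouse
    fUltra: 0.13
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: purkinje-P0
    species: mouse
    fUltra: 0.09
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: purkinje-adult
    species: mouse
    fUltra: 0.10
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: microglia-human
    species: human
    fUltra: 0.34
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: microglia-mouse
    species: mouse
    fUltra: 0.34
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: oligodendrocyte-human
    species: human
    fUltra: 0.29
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
  - name: oligodendrocyte-mouse
    species: mouse
    fUltra: 0.27
    alpha: 1.0
    fInter: 0.10
    rho: 0.7
    drift: 0.0
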