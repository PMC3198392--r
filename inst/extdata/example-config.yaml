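# Example analysis configuration for `snphapscan run-all --config ...`
# Unset keys fall back to package defaults. Either give `input:` paths
# (ped/map + subject table) or let `simulate:` build a synthetic study.
simulate:
  enabled: true
  seed: 1
minp:
  B: 999
  seed: 1
  strata: center
haplowalk:
  width: 3
  fdrThreshold: 0.1
poolThreshold: 0.05
blocks:
  SLC19A1_block1: [rs12483553, rs2838950, rs2838951, rs17004785]
stratifyBy: [vegetableTertile, alcoholTertile]
outputDir: snphapscan-out
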