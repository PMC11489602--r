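# Synthetic, illustrative cohort recipe: marginal prevalences follow the
# published young-cohort profile (n = 529, 24 variables), and the latent
# dependency block plants the published strongest-link magnitudes on top
# of a background complex-tic cluster correlation. It is NOT an estimate
# of the real joint distribution.
n_patients: 529
cohort_label: young-like
seed: 1
prevalences:
  simple motor tics: 0.9981096
  simple vocal tics: 0.9413989
  complex motor tics: 0.5198488
  complex vocal tics: 0.4744802
  coprolalia: 0.2136106
  copropraxia: 0.1512287
  palilalia: 0.2967864
  echolalia: 0.2457467
  echopraxia: 0.1663516
  touching people: 0.2381853
  touching objects: 0.3648393
  obsessions: 0.1984877
  compulsions: 0.5671078
  anxiety: 0.2816635
  depression: 0.0775047
  substance use disorder: 0.0056711
  premonitory urges: 0.5595463
  tic suppression: 0.7391304
  hyperactivity: 0.289225
  inattention: 0.4442344
  self-injurious behavior: 0.3383743
  aggression toward others: 0.1115312
  impulsivity: 0.5992439
  sleep disorders: 0.221172
latent:
  simple motor tics:
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  simple vocal tics:
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  complex motor tics:
  - '0'
  - '0'
  - '1'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.76074218673925786'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  complex vocal tics:
  - '0'
  - '0'
  - '0.65000000000000002'
  - '1'
  - '0.87145996006604021'
  - '0.65000000000000002'
  - '0.80053710857446292'
  - '0.82141113199108884'
  - '0.65000000000000002'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  coprolalia:
  - '0'
  - '0'
  - '0.65000000000000002'
  - '0.87145996006604021'
  - '1'
  - '0.81176757731323257'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  copropraxia:
  - '0'
  - '0'
  - '0.76074218673925786'
  - '0.65000000000000002'
  - '0.81176757731323257'
  - '1'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  palilalia:
  - '0'
  - '0'
  - '0.65000000000000002'
  - '0.80053710857446292'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '1'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  echolalia:
  - '0'
  - '0'
  - '0.65000000000000002'
  - '0.82141113199108884'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '1'
  - '0.73059081958190908'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  echopraxia:
  - '0'
  - '0'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.65000000000000002'
  - '0.73059081958190908'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  touching people:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  touching objects:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  obsessions:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  compulsions:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  anxiety:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  depression:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  substance use disorder:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  premonitory urges:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0.53124999946875007'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  tic suppression:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0.53124999946875007'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  hyperactivity:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0.79821777263928229'
  - '0'
  - '0'
  - '0'
  - '0'
  inattention:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0.79821777263928229'
  - '1'
  - '0'
  - '0'
  - '0'
  - '0'
  self-injurious behavior:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  - '0'
  aggression toward others:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  - '0'
  impulsivity:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
  - '0'
  sleep disorders:
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '0'
  - '1'
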