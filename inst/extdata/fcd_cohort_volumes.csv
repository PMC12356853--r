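# Reference volumes (mm^3, 1 mm^3 voxels) from a surgical pediatric FCD
# type II cohort of 23 subjects: manually outlined radiological lesion
# (PRR), automatically detected post-resection cavity (PRC), and their
# overlap. Percent overlay = 100 * overlap / PRC, reported to one decimal.
# Subjects without a radiologically visible lesion have no PRR. Subj02's
# individually reported cavity entry is internally inconsistent; its PRC
# volume is reconstructed from the cohort mean and its overlap fields are
# left missing (see the note column).
subject,prr_mm3,prc_mm3,overlap_mm3,percent_overlay,note
Subj01,NA,14769,NA,NA,no PRR
Subj02,3466,13758,NA,NA,prc reconstructed from cohort mean; overlap entry inconsistent
Subj03,1164,21046,137,0.7,
Subj04,863,13798,0,0.0,
Subj05,781,14029,685,4.9,
Subj06,3691,26929,2902,10.8,
Subj07,847,7920,127,1.6,
Subj08,NA,4287,NA,NA,no PRR
Subj09,4701,3124,0,0.0,
Subj10,1072,6274,453,7.2,
Subj11,NA,6365,NA,NA,no PRR
Subj12,2558,18720,2211,11.8,
Subj13,NA,9450,NA,NA,no PRR
Subj14,NA,14781,NA,NA,no PRR
Subj15,1217,42860,0,0.0,
Subj16,3202,5999,745,12.4,
Subj17,727,9432,447,4.7,
Subj18,574,9690,449,4.6,
Subj19,1593,3096,1056,34.1,
Subj20,NA,12114,NA,NA,no PRR
Subj21,1901,5307,351,6.6,
Subj22,866,2385,0,0.0,
Subj23,1053,52716,0,0.0,
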