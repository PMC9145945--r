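#################################################################
# If you used AutoDock Vina in your work, please cite:          #
# (synthetic log: crystal-ligand redock into the PDL1 dimer     #
#  pocket, constructed for parser tests; not a real run)        #
#################################################################

Detected 1 CPU
Reading input ... done.
Setting up the scoring function ... done.
Analyzing the binding site ... done.
Using random seed: 20220516
Performing search ... done.
Refining results ... done.

mode |   affinity | dist from best mode
     | (kcal/mol) | rmsd l.b.| rmsd u.b.
-----+------------+----------+----------
   1       -11.4      0.000      0.000
   2       -10.8      1.712      2.341
   3       -10.1      2.905      4.118
   4        -9.7      3.644      5.027
   5        -9.2      4.101      6.332

Writing output ... done.
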