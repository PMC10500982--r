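# synthetic FreeSolv-style benchmark fixture (toy data, not the real database)
# columns: id; SMILES; name; experimental ASFE (kcal/mol); expt uncertainty; calculated ASFE; calc uncertainty
toy_000001; CCO; synthetic-01; 0.81; 0.42; 1.71; 0.14
toy_000002; CCCO; synthetic-02; 1.12; 0.05; 1.01; 0.15
toy_000003; CCCCO; synthetic-03; -7.99; 0.16; -10.71; 0.19
toy_000004; c1ccccc1; synthetic-04; -0.37; 0.56; -2.85; 0.20
toy_000005; Cc1ccccc1; synthetic-05; -3.02; 0.56; -1.37; 0.23
toy_000006; CCN; synthetic-06; -4.73; 0.45; -4.87; 0.15
toy_000007; CCC(=O)O; synthetic-07; -1.69; 0.23; -3.45; 0.28
toy_000008; CC(C)O; synthetic-08; -10.11; 0.33; -10.10; 0.29
toy_000009; CCOCC; synthetic-09; -2.80; 0.46; -1.26; 0.11
toy_000010; CC(=O)C; synthetic-10; -2.13; 0.39; 0.15; 0.23
toy_000011; c1ccncc1; synthetic-11; -5.59; 0.39; -5.86; 0.28
toy_000012; CCCl; synthetic-12; -1.93; 0.17; -2.01; 0.20
toy_000013; ClCCCl; synthetic-13; 1.09; 0.17; -0.65; 0.21
toy_000014; CCBr; synthetic-14; -8.42; 0.26; -7.71; 0.28
toy_000015; CC(N)=O; synthetic-15; -5.53; 0.57; -6.03; 0.26
toy_000016; CCCC; synthetic-16; 1.16; 0.58; 1.86; 0.19
toy_000017; CCCCC; synthetic-17; 1.70; 0.46; 2.68; 0.26
toy_000018; CCCCCC; synthetic-18; -10.36; 0.45; -9.02; 0.08
toy_000019; OCC(O)CO; synthetic-19; -5.35; 0.34; -5.82; 0.24
toy_000020; CC(C)(C)O; synthetic-20; -4.16; 0.05; -3.40; 0.21
toy_000021; c1ccc(O)cc1; synthetic-21; 0.66; 0.38; -1.03; 0.09
toy_000022; CCSCC; synthetic-22; -10.06; 0.51; -10.72; 0.07
toy_000023; CC#N; synthetic-23; 1.84; 0.46; 1.10; 0.17
toy_000024; CCF; synthetic-24; 1.25; 0.30; -1.21; 0.24
toy_000025; c1ccc(N)cc1; synthetic-25; -10.85; 0.34; -10.61; 0.23
toy_000026; CC(C)C; synthetic-26; -4.80; 0.35; -4.37; 0.25
toy_000027; CCCN; synthetic-27; -6.54; 0.05; -6.74; 0.09
toy_000028; COC; synthetic-28; 0.68; 0.25; 1.71; 0.29
toy_000029; CCOC(=O)C; synthetic-29; -5.74; 0.39; -6.34; 0.12
toy_000030; C1CCCCC1; synthetic-30; -0.30; 0.51; -1.61; 0.09
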