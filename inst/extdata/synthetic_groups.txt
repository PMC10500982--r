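# synthetic groups fixture: id; first category[; more]
toy_000001; alcohol
toy_000002; alcohol
toy_000003; alcohol; polyfunctional
toy_000004; aromatic
toy_000005; aromatic
toy_000006; amine; polyfunctional
toy_000007; acid
toy_000008; alcohol
toy_000009; ether; polyfunctional
toy_000010; ketone
toy_000011; aromatic
toy_000012; alkyl chloride; polyfunctional
toy_000013; alkyl chloride
toy_000014; alkyl bromide
toy_000015; amide; polyfunctional
toy_000016; alkane
toy_000017; alkane
toy_000018; alkane; polyfunctional
toy_000019; alcohol
toy_000020; alcohol
toy_000021; alcohol; polyfunctional
toy_000022; thioether
toy_000023; nitrile
toy_000024; fluoride; polyfunctional
toy_000025; amine
toy_000026; alkane
toy_000027; amine; polyfunctional
toy_000028; ether
toy_000029; ester
toy_000030; alkane; polyfunctional
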