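0.9694601966639035 -0.0507162521270272 -0.4114951824046288 -0.1658538929458459 0.2295393059671713 -0.0902077709067369 0.4023779584522443 0.6725421576232928 0.8833398187660527 -0.5960904808101221 0.7138654268751570 0.1253714402080808 0.7236285890440729 -0.5059392748255915 0.4719565844889952 0.2067280428149462 0.5752884883006421 0.8087054476584850 0.9294764809582128
0.0663812868871804 0.9946312340686592 0.8328186393630238 0.5468908793646942 0.0653241311450692 -0.3154221620215152 -0.5360597501333908 0.4775807819262975 -0.4685568613187374 0.7597470995959177 -0.1235549729804241 0.8070933471677501 -0.4226341021423668 0.0726768257705391 0.8681898118490039 0.8849321883196789 0.4625816920498905 0.5619479652687149 0.1423840892747750
0.2360941588341131 -0.0902029377861047 0.3702496843851493 0.8206112674478819 0.9711047651547443 0.9446541260025865 0.7421131469248679 -0.5653349829561868 0.0128542714103420 -0.2597315601600008 0.6892969758849639 -0.5769595574541678 -0.5456574757339989 0.8595019076097932 -0.1533082938365466 0.4173230623745183 0.6745823399771314 0.1738101931931513 -0.3402943468042483
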